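#include <Rcpp.h>
#include <cstring>
#include <set>
using namespace Rcpp;

// Affine-gap local alignment with a caller-supplied substitution matrix.
// Gap of length L scores gap_open + (L - 1) * gap_extend.
// Traceback tie-break: diagonal, then up (gap in ref), then left (gap in query);
// among equal-scoring end cells the smallest (i, j) wins.

static inline int idx_of(char c, const std::string &alphabet) {
  size_t p = alphabet.find(c);
  if (p == std::string::npos) return -1;
  return (int)p;
}

// [[Rcpp::export]]
List cpp_sw_align(std::string q, std::string r, std::string alphabet,
                  IntegerMatrix smat, int gap_open, int gap_extend) {
  const int n = q.size(), m = r.size();
  std::vector<int> qi(n), ri(m);
  for (int i = 0; i < n; ++i) {
    qi[i] = idx_of(q[i], alphabet);
    if (qi[i] < 0) stop("residue '%s' at query position %d outside scoring alphabet",
                        std::string(1, q[i]).c_str(), i + 1);
  }
  for (int j = 0; j < m; ++j) {
    ri[j] = idx_of(r[j], alphabet);
    if (ri[j] < 0) stop("residue '%s' at reference position %d outside scoring alphabet",
                        std::string(1, r[j]).c_str(), j + 1);
  }
  const int NEG = -1000000000;
  // M: ends in a substitution column; X: gap in ref (consumes query); Y: gap in query.
  std::vector<int> M((n + 1) * (m + 1), 0), X((n + 1) * (m + 1), NEG),
      Y((n + 1) * (m + 1), NEG);
  auto at = [m](int i, int j) { return i * (m + 1) + j; };
  int best = 0, bi = 0, bj = 0;
  for (int i = 1; i <= n; ++i) {
    for (int j = 1; j <= m; ++j) {
      int s = smat(qi[i - 1], ri[j - 1]);
      int diag = std::max(std::max(M[at(i - 1, j - 1)], X[at(i - 1, j - 1)]),
                          Y[at(i - 1, j - 1)]);
      int mv = std::max(0, diag + s);
      M[at(i, j)] = mv;
      int xo = M[at(i - 1, j)] + gap_open;
      int xe = X[at(i - 1, j)] == NEG ? NEG : X[at(i - 1, j)] + gap_extend;
      X[at(i, j)] = std::max(xo, xe);
      int yo = M[at(i, j - 1)] + gap_open;
      int ye = Y[at(i, j - 1)] == NEG ? NEG : Y[at(i, j - 1)] + gap_extend;
      Y[at(i, j)] = std::max(yo, ye);
      if (mv > best) { best = mv; bi = i; bj = j; }
    }
  }
  std::vector<int> qcol, rcol;  // 1-based indices, 0 marks a gap
  if (best > 0) {
    int i = bi, j = bj, state = 0;  // 0=M, 1=X, 2=Y
    while (true) {
      if (state == 0) {
        int v = M[at(i, j)];
        if (v <= 0) break;
        qcol.push_back(i); rcol.push_back(j);
        int s = smat(qi[i - 1], ri[j - 1]);
        int prev = v - s;
        --i; --j;
        if (prev == 0 && M[at(i, j)] != prev && X[at(i, j)] != prev &&
            Y[at(i, j)] != prev) break;
        if (M[at(i, j)] == prev) state = 0;
        else if (X[at(i, j)] == prev) state = 1;
        else if (Y[at(i, j)] == prev) state = 2;
        else break;  // came from the implicit 0 start
      } else if (state == 1) {
        qcol.push_back(i); rcol.push_back(0);
        int v = X[at(i, j)];
        --i;
        if (M[at(i, j)] + gap_open == v) state = 0; else state = 1;
      } else {
        qcol.push_back(0); rcol.push_back(j);
        int v = Y[at(i, j)];
        --j;
        if (M[at(i, j)] + gap_open == v) state = 0; else state = 2;
      }
    }
    std::reverse(qcol.begin(), qcol.end());
    std::reverse(rcol.begin(), rcol.end());
  }
  int qs = 0, qe = 0, rs = 0, re = 0;
  for (size_t k = 0; k < qcol.size(); ++k) {
    if (qcol[k] > 0) { if (qs == 0) qs = qcol[k]; qe = qcol[k]; }
    if (rcol[k] > 0) { if (rs == 0) rs = rcol[k]; re = rcol[k]; }
  }
  IntegerVector qv(qcol.size()), rv(rcol.size());
  for (size_t k = 0; k < qcol.size(); ++k) {
    qv[k] = qcol[k] == 0 ? NA_INTEGER : qcol[k];
    rv[k] = rcol[k] == 0 ? NA_INTEGER : rcol[k];
  }
  return List::create(_["score"] = best, _["q_start"] = qs, _["q_end"] = qe,
                      _["r_start"] = rs, _["r_end"] = re, _["q_idx"] = qv,
                      _["r_idx"] = rv);
}

// Local protein-to-DNA alignment with frameshift moves. Codon steps consume
// 1/2/3/4/5 nt; any step != 3 nt is a frameshift and pays fs_penalty. The
// residue score for a step ending at DNA position j uses the translation of
// dna[j-2..j]. Unaligned protein residues / extra DNA codons pay gap_penalty.
// [[Rcpp::export]]
List cpp_frameshift_align(std::string prot, std::string dna, std::string alphabet,
                          IntegerMatrix smat, CharacterVector codons,
                          CharacterVector aas, int fs_penalty, int gap_penalty) {
  const int n = prot.size(), m = dna.size();
  // codon lookup: index c1*16+c2*4+c3 over ACGT; anything else -> 'X'
  std::vector<char> clut(64, 'X');
  for (int k = 0; k < codons.size(); ++k) {
    std::string c = as<std::string>(codons[k]);
    std::string a = as<std::string>(aas[k]);
    int v = 0; bool ok = true;
    for (int t = 0; t < 3; ++t) {
      int b;
      switch (c[t]) { case 'A': b = 0; break; case 'C': b = 1; break;
                      case 'G': b = 2; break; case 'T': b = 3; break;
                      default: b = -1; }
      if (b < 0) { ok = false; break; }
      v = v * 4 + b;
    }
    if (ok) clut[v] = a[0];
  }
  std::vector<int> base(m, -1);
  for (int j = 0; j < m; ++j) {
    switch (dna[j]) { case 'A': base[j] = 0; break; case 'C': base[j] = 1; break;
                      case 'G': base[j] = 2; break; case 'T': base[j] = 3; break;
                      default: base[j] = -1; }
  }
  auto tr = [&](int j) -> char {  // translation of dna[j-2..j], 1-based j
    if (j < 3) return 'X';
    int b1 = base[j - 3], b2 = base[j - 2], b3 = base[j - 1];
    if (b1 < 0 || b2 < 0 || b3 < 0) return 'X';
    return clut[b1 * 16 + b2 * 4 + b3];
  };
  std::vector<int> pi(n);
  for (int i = 0; i < n; ++i) {
    pi[i] = idx_of(prot[i], alphabet);
    if (pi[i] < 0) stop("residue '%s' outside scoring alphabet",
                        std::string(1, prot[i]).c_str());
  }
  const int steps[5] = {3, 1, 2, 4, 5};  // in-frame move preferred on ties
  // deletion steps leave a broken codon of 1-2 nt; score it as the best
  // single completion (the missing base could be anything, anywhere)
  std::vector<std::vector<char>> c2aa(m + 1), c1aa(m + 1);
  for (int j = 1; j <= m; ++j) {
    std::set<char> s2, s1;
    if (j >= 2 && base[j - 2] >= 0 && base[j - 1] >= 0) {
      int b1 = base[j - 2], b2 = base[j - 1];
      for (int pos = 0; pos < 3; ++pos) {
        for (int nb = 0; nb < 4; ++nb) {
          int c[3];
          if (pos == 0) { c[0] = nb; c[1] = b1; c[2] = b2; }
          else if (pos == 1) { c[0] = b1; c[1] = nb; c[2] = b2; }
          else { c[0] = b1; c[1] = b2; c[2] = nb; }
          s2.insert(clut[c[0] * 16 + c[1] * 4 + c[2]]);
        }
      }
    }
    if (base[j - 1] >= 0) {
      int b = base[j - 1];
      for (int pos = 0; pos < 3; ++pos) {
        for (int n1 = 0; n1 < 4; ++n1) {
          for (int n2 = 0; n2 < 4; ++n2) {
            int c[3];
            if (pos == 0) { c[0] = b; c[1] = n1; c[2] = n2; }
            else if (pos == 1) { c[0] = n1; c[1] = b; c[2] = n2; }
            else { c[0] = n1; c[1] = n2; c[2] = b; }
            s1.insert(clut[c[0] * 16 + c[1] * 4 + c[2]]);
          }
        }
      }
    }
    c2aa[j].assign(s2.begin(), s2.end());
    c1aa[j].assign(s1.begin(), s1.end());
  }
  std::vector<int> H((n + 1) * (m + 1), 0);
  std::vector<signed char> trace((n + 1) * (m + 1), 0);  // 1..5 codon step, 6 prot gap, 7 dna gap
  auto at = [m](int i, int j) { return i * (m + 1) + j; };
  int best = 0, bi = 0, bj = 0;
  for (int i = 1; i <= n; ++i) {
    for (int j = 1; j <= m; ++j) {
      int v = 0; signed char tb = 0;
      char aa = tr(j);
      int ai = idx_of(aa, alphabet);
      for (int k = 0; k < 5; ++k) {
        int c = steps[k];
        if (j - c < 0) continue;
        int s;
        if (c == 2 || c == 1) {
          const std::vector<char> &cand_aa = (c == 2) ? c2aa[j] : c1aa[j];
          s = -1000000;
          for (char a : cand_aa) {
            int aidx = idx_of(a, alphabet);
            if (aidx >= 0 && smat(pi[i - 1], aidx) > s)
              s = smat(pi[i - 1], aidx);
          }
          if (s == -1000000) s = 0;
        } else {
          s = (ai >= 0) ? smat(pi[i - 1], ai) : 0;
        }
        int cand = H[at(i - 1, j - c)] + s - (c != 3 ? fs_penalty : 0);
        if (cand > v) { v = cand; tb = (signed char)c; }
      }
      int cand = H[at(i - 1, j)] - gap_penalty;
      if (cand > v) { v = cand; tb = 6; }
      if (j >= 3) {
        cand = H[at(i, j - 3)] - gap_penalty;
        if (cand > v) { v = cand; tb = 7; }
      }
      H[at(i, j)] = v; trace[at(i, j)] = tb;
      if (v > best) { best = v; bi = i; bj = j; }
    }
  }
  std::vector<int> ev_pos, ev_len; std::vector<std::string> ev_kind;
  int ps = bi, pe = bi, ds = bj, de = bj;
  if (best > 0) {
    int i = bi, j = bj;
    while (i > 0 && j > 0 && H[at(i, j)] > 0) {
      signed char tb = trace[at(i, j)];
      if (tb == 0) break;
      ps = i; ds = j;
      if (tb >= 1 && tb <= 5) {
        if (tb != 3) {
          ev_pos.push_back(j - tb + 1);  // 1-based start of the shifted step
          ev_len.push_back(std::abs((int)tb - 3));
          ev_kind.push_back(tb < 3 ? "deletion" : "insertion");
        }
        --i; j -= tb;
        ds = j + 1;
      } else if (tb == 6) { --i; }
      else { j -= 3; ds = j + 1; }
    }
    std::reverse(ev_pos.begin(), ev_pos.end());
    std::reverse(ev_len.begin(), ev_len.end());
    std::reverse(ev_kind.begin(), ev_kind.end());
  } else { ps = pe = ds = de = 0; }
  return List::create(_["score"] = best, _["prot_start"] = ps, _["prot_end"] = pe,
                      _["dna_start"] = ds, _["dna_end"] = de,
                      _["event_pos"] = wrap(ev_pos), _["event_len"] = wrap(ev_len),
                      _["event_kind"] = wrap(ev_kind));
}
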