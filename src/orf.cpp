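#include <Rcpp.h>
#include <unordered_set>
#include <set>
using namespace Rcpp;

// Read-through ORF enumeration on the three forward frames of one sequence.
// Within each maximal segment bounded by TAA/TAG (or sequence ends), every
// start (segment start, or the codon after each internal TGA) is extended as
// far right as <= K internal TGAs allow; the maximal extension is emitted
// together with every prefix that instead terminates at an internal TGA.
// N-containing codons translate to 'X' and never act as stops.
// [[Rcpp::export]]
List cpp_enumerate_orfs(std::string seq, int K, int min_aa, bool require_atg,
                        CharacterVector codons, CharacterVector aas) {
  const int n = seq.size();
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
  std::vector<int> base(n);
  for (int j = 0; j < n; ++j) {
    switch (seq[j]) { case 'A': base[j] = 0; break; case 'C': base[j] = 1; break;
                      case 'G': base[j] = 2; break; case 'T': base[j] = 3; break;
                      case 'N': base[j] = 4; break;
                      default:
                        stop("non-ACGTN character '%s' at offset %d",
                             std::string(1, seq[j]).c_str(), j); }
  }
  std::vector<int> o_start, o_end, o_frame;
  std::vector<std::string> o_pep, o_term;
  List o_tga;
  std::vector<IntegerVector> tga_list;

  for (int f = 0; f < 3; ++f) {
    int ncod = (n - f) / 3;
    if (ncod <= 0) continue;
    // codes: 0..63 codon index, -1 contains N
    std::vector<int> code(ncod);
    std::vector<char> aa(ncod);
    for (int k = 0; k < ncod; ++k) {
      int b1 = base[f + 3 * k], b2 = base[f + 3 * k + 1], b3 = base[f + 3 * k + 2];
      if (b1 > 3 || b2 > 3 || b3 > 3) { code[k] = -1; aa[k] = 'X'; }
      else { code[k] = b1 * 16 + b2 * 4 + b3; aa[k] = clut[code[k]]; }
    }
    const int TAA = 0 * 16 + 0 * 4 + 0 + 48;  // T=3: 3*16=48 -> TAA = 48+0+0
    const int TAG = 48 + 0 + 2;
    const int TGA = 48 + 2 * 4 + 0;
    int segs = 0;
    int s = 0;
    while (s <= ncod) {
      // segment [s, e) up to next hard stop or end
      int e = s;
      while (e < ncod && code[e] != TAA && code[e] != TAG) ++e;
      bool hard = (e < ncod);
      // TGA positions within [s, e)
      std::vector<int> tg;
      for (int k = s; k < e; ++k) if (code[k] == TGA) tg.push_back(k);
      int m = tg.size();
      std::set<std::pair<int,int>> seen;  // (cs, ce) codon intervals emitted
      for (int a = 0; a <= m; ++a) {
        int cs = (a == 0) ? s : tg[a - 1] + 1;
        if (require_atg) {
          const int ATG = 0 * 16 + 3 * 4 + 2 + 0;  // A=0,T=3,G=2 -> 0*16+3*4+2
          while (cs < e && code[cs] != ATG && code[cs] != TGA) ++cs;
          if (cs >= e || code[cs] == TGA) continue;
        }
        // internal TGAs at/after cs
        int a2 = a;
        while (a2 < m && tg[a2] < cs) ++a2;
        // prefix ends terminating at each reachable internal TGA
        for (int j = a2; j < m && j - a2 < (K + 1); ++j) {
          int ce = tg[j];
          if (ce - cs >= min_aa && seen.insert({cs, ce}).second) {
            std::string pep(ce - cs, 'X');
            IntegerVector offs;
            for (int k = cs; k < ce; ++k) {
              pep[k - cs] = (code[k] == TGA) ? 'U' : aa[k];
              if (code[k] == TGA) offs.push_back(k - cs);
            }
            o_start.push_back(f + 3 * cs); o_end.push_back(f + 3 * ce);
            o_frame.push_back(f); o_pep.push_back(pep); o_term.push_back("TGA");
            tga_list.push_back(offs);
          }
        }
        // maximal extension: only valid if all remaining TGAs fit in K
        if (m - a2 <= K) {
          int ce = e;
          if (ce - cs >= min_aa && seen.insert({cs, ce}).second) {
            std::string pep(ce - cs, 'X');
            IntegerVector offs;
            for (int k = cs; k < ce; ++k) {
              pep[k - cs] = (code[k] == TGA) ? 'U' : aa[k];
              if (code[k] == TGA) offs.push_back(k - cs);
            }
            std::string term = "";
            if (hard) term = (code[e] == TAA) ? "TAA" : "TAG";
            o_start.push_back(f + 3 * cs); o_end.push_back(f + 3 * ce);
            o_frame.push_back(f); o_pep.push_back(pep); o_term.push_back(term);
            tga_list.push_back(offs);
          }
        }
      }
      ++segs;
      s = e + 1;
      if (!hard) break;
    }
  }
  List tl(tga_list.size());
  for (size_t k = 0; k < tga_list.size(); ++k) tl[k] = tga_list[k];
  return List::create(_["start"] = wrap(o_start), _["end"] = wrap(o_end),
                      _["frame"] = wrap(o_frame), _["peptide"] = wrap(o_pep),
                      _["terminal_stop"] = wrap(o_term), _["tga_offsets"] = tl);
}

// TRUE for each peptide sharing at least one k-mer with the reference set.
// [[Rcpp::export]]
LogicalVector cpp_kmer_filter(CharacterVector peptides, CharacterVector ref_kmers,
                              int k) {
  std::unordered_set<std::string> refs;
  for (int i = 0; i < ref_kmers.size(); ++i)
    refs.insert(as<std::string>(ref_kmers[i]));
  LogicalVector out(peptides.size());
  for (int i = 0; i < peptides.size(); ++i) {
    std::string p = as<std::string>(peptides[i]);
    bool hit = false;
    if ((int)p.size() >= k) {
      for (size_t j = 0; j + k <= p.size(); ++j) {
        if (refs.count(p.substr(j, k))) { hit = true; break; }
      }
    }
    out[i] = hit;
  }
  return out;
}
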