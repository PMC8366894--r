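// Affine-gap pairwise alignment and pileup primitives for amplicon-scale
// references (<= ~1 kb). Three-state Gotoh DP; deterministic tie-breaking:
// substitution preferred over gap, then a fixed traceback state order.
#include <Rcpp.h>
#include <cstring>
#include <map>
using namespace Rcpp;

static const int NEG = -1000000000;

// IUPAC nucleotide bitmasks: A=1, C=2, G=4, T=8
static int iupac_mask_tab[256];
static bool iupac_init_done = false;

static void init_iupac() {
  if (iupac_init_done) return;
  std::memset(iupac_mask_tab, 0, sizeof(iupac_mask_tab));
  const char *codes = "ACGTRYSWKMBDHVN";
  const int masks[] = {1, 2, 4, 8, 5, 10, 6, 9, 12, 3, 14, 13, 11, 7, 15};
  for (int i = 0; codes[i]; ++i) {
    iupac_mask_tab[(unsigned char)codes[i]] = masks[i];
    iupac_mask_tab[(unsigned char)std::tolower(codes[i])] = masks[i];
  }
  iupac_init_done = true;
}

static inline int subst_score(char a, char b, int match, int mismatch, bool iupac) {
  if (iupac) {
    int ma = iupac_mask_tab[(unsigned char)a], mb = iupac_mask_tab[(unsigned char)b];
    return (ma & mb) ? match : mismatch;
  }
  return (a == b) ? match : mismatch;
}

// States: 0 = M (diagonal), 1 = Ix (gap in b, consumes a), 2 = Iy (gap in a,
// consumes b). Gap of length L costs open + L * extend.
// mode: 0 global; 1 overlap (ends-free in both sequences);
//       2 semi-global (a fully aligned, b end gaps free).
static List align_core(const std::string &a, const std::string &b,
                       int match, int mismatch, int gap_open, int gap_extend,
                       int mode, bool iupac) {
  init_iupac();
  const int n = a.size(), m = b.size();
  const int go = gap_open + gap_extend; // cost of first gapped base
  const int ge = gap_extend;

  std::vector<int> M((n + 1) * (m + 1)), Ix((n + 1) * (m + 1)), Iy((n + 1) * (m + 1));
  std::vector<unsigned char> tbM((n + 1) * (m + 1)), tbIx((n + 1) * (m + 1)),
      tbIy((n + 1) * (m + 1));
  auto at = [m](int i, int j) { return i * (m + 1) + j; };

  // borders
  M[at(0, 0)] = 0; Ix[at(0, 0)] = NEG; Iy[at(0, 0)] = NEG;
  for (int i = 1; i <= n; ++i) {
    M[at(i, 0)] = (mode == 1) ? 0 : NEG;
    Ix[at(i, 0)] = (mode == 1) ? NEG : -(gap_open + ge * i);
    Iy[at(i, 0)] = NEG;
    tbIx[at(i, 0)] = 1;
  }
  for (int j = 1; j <= m; ++j) {
    M[at(0, j)] = (mode == 0) ? NEG : 0; // free b-prefix for overlap/semi-global
    Iy[at(0, j)] = (mode == 0) ? -(gap_open + ge * j) : NEG;
    Ix[at(0, j)] = NEG;
    tbIy[at(0, j)] = 2;
  }

  for (int i = 1; i <= n; ++i) {
    for (int j = 1; j <= m; ++j) {
      const int d = at(i - 1, j - 1), u = at(i - 1, j), l = at(i, j - 1), c = at(i, j);
      // M: preference order M > Ix > Iy on ties
      int s = subst_score(a[i - 1], b[j - 1], match, mismatch, iupac);
      int best = M[d]; unsigned char st = 0;
      if (Ix[d] > best) { best = Ix[d]; st = 1; }
      if (Iy[d] > best) { best = Iy[d]; st = 2; }
      M[c] = (best <= NEG / 2) ? NEG : best + s; tbM[c] = st;
      // Ix: gap in b (vertical)
      int vM = M[u] - go, vIx = Ix[u] - ge, vIy = Iy[u] - go;
      best = vM; st = 0;
      if (vIx > best) { best = vIx; st = 1; }
      if (vIy > best) { best = vIy; st = 2; }
      Ix[c] = (best <= NEG / 2) ? NEG : best; tbIx[c] = st;
      // Iy: gap in a (horizontal)
      int hM = M[l] - go, hIy = Iy[l] - ge, hIx = Ix[l] - go;
      best = hM; st = 0;
      if (hIx > best) { best = hIx; st = 1; }
      if (hIy > best) { best = hIy; st = 2; }
      Iy[c] = (best <= NEG / 2) ? NEG : best; tbIy[c] = st;
    }
  }

  // pick end cell
  int ei = n, ej = m, estate = 0, escore = NEG;
  auto consider = [&](int i, int j) {
    const int c = at(i, j);
    int sc[3] = {M[c], Ix[c], Iy[c]};
    for (int s = 0; s < 3; ++s)
      if (sc[s] > escore) { escore = sc[s]; estate = s; ei = i; ej = j; }
  };
  if (mode == 0) {
    consider(n, m);
  } else if (mode == 2) {
    for (int j = 0; j <= m; ++j) consider(n, j); // a fully consumed; leftmost end wins ties
  } else { // overlap: last row and last column
    for (int j = 0; j <= m; ++j) consider(n, j);
    for (int i = 0; i < n; ++i) consider(i, m);
  }

  // traceback
  std::string aa, bb;
  int i = ei, j = ej, state = estate;
  // trailing free gaps (overlap mode keeps unaligned tails as gap columns)
  if (mode == 1) {
    for (int k = n; k > ei; --k) { aa.push_back(a[k - 1]); bb.push_back('-'); }
    for (int k = m; k > ej; --k) { aa.push_back('-'); bb.push_back(b[k - 1]); }
  }
  while (i > 0 || j > 0) {
    if ((mode != 0) && i == 0) break;           // free b-prefix
    if (mode == 1 && j == 0) break;             // free a-prefix (overlap)
    const int c = at(i, j);
    if (state == 0) {
      if (i == 0 || j == 0) break;
      aa.push_back(a[i - 1]); bb.push_back(b[j - 1]);
      state = tbM[c]; --i; --j;
    } else if (state == 1) {
      aa.push_back(a[i - 1]); bb.push_back('-');
      state = tbIx[c]; --i;
    } else {
      aa.push_back('-'); bb.push_back(b[j - 1]);
      state = tbIy[c]; --j;
    }
  }
  int b_start = j; // for semi-global: offset of alignment start in b
  if (mode == 1) { // leading free tails
    while (i > 0) { aa.push_back(a[i - 1]); bb.push_back('-'); --i; }
    while (j > 0) { aa.push_back('-'); bb.push_back(b[j - 1]); --j; }
  }
  std::reverse(aa.begin(), aa.end());
  std::reverse(bb.begin(), bb.end());

  return List::create(_["a"] = aa, _["b"] = bb, _["score"] = escore,
                      _["b_start"] = b_start, _["b_end"] = ej);
}

// [[Rcpp::export]]
List cpp_align(std::string a, std::string b, int match, int mismatch,
               int gap_open, int gap_extend, int mode, bool iupac) {
  return align_core(a, b, match, mismatch, gap_open, gap_extend, mode, iupac);
}

// Semi-global placement of each read within a reference; returns per-read
// start (0-based), score, aligned strings, and column tallies.
// [[Rcpp::export]]
List cpp_map_reads(CharacterVector reads, std::string ref, int match,
                   int mismatch, int gap_open, int gap_extend) {
  const int nr = reads.size();
  IntegerVector start(nr), score(nr), mism(nr), gaps(nr), alncols(nr);
  CharacterVector ar(nr), rr(nr);
  for (int k = 0; k < nr; ++k) {
    std::string rd = as<std::string>(reads[k]);
    List al = align_core(rd, ref, match, mismatch, gap_open, gap_extend, 2, false);
    std::string aa = al["a"], bb = al["b"];
    int nm = 0, ng = 0;
    for (size_t c = 0; c < aa.size(); ++c) {
      if (aa[c] == '-' || bb[c] == '-') ++ng;
      else if (aa[c] != bb[c]) ++nm;
    }
    start[k] = as<int>(al["b_start"]);
    score[k] = as<int>(al["score"]);
    mism[k] = nm; gaps[k] = ng; alncols[k] = aa.size();
    ar[k] = aa; rr[k] = bb;
  }
  return List::create(_["start"] = start, _["score"] = score,
                      _["mismatches"] = mism, _["gaps"] = gaps,
                      _["aln_cols"] = alncols, _["aligned_read"] = ar,
                      _["aligned_ref"] = rr);
}

// Per-position tallies of A/C/G/T/deletion plus an insertion catalogue
// (anchored to the reference position left of the inserted bases).
// [[Rcpp::export]]
List cpp_pileup(IntegerVector starts, CharacterVector aligned_read,
                CharacterVector aligned_ref, int ref_len) {
  IntegerMatrix counts(5, ref_len); // rows A,C,G,T,del
  std::map<std::pair<int, std::string>, int> ins;
  for (int k = 0; k < starts.size(); ++k) {
    std::string ar = as<std::string>(aligned_read[k]);
    std::string rr = as<std::string>(aligned_ref[k]);
    int pos = starts[k];
    std::string pending;
    int pending_anchor = -2;
    for (size_t c = 0; c < ar.size(); ++c) {
      if (rr[c] == '-') { // insertion in read
        if (pending_anchor != pos - 1) { pending.clear(); pending_anchor = pos - 1; }
        pending.push_back(ar[c]);
        continue;
      }
      if (!pending.empty()) {
        if (pending_anchor >= 0) ++ins[{pending_anchor, pending}];
        pending.clear(); pending_anchor = -2;
      }
      if (pos >= 0 && pos < ref_len) {
        switch (ar[c]) {
          case 'A': ++counts(0, pos); break;
          case 'C': ++counts(1, pos); break;
          case 'G': ++counts(2, pos); break;
          case 'T': ++counts(3, pos); break;
          case '-': ++counts(4, pos); break;
          default: break; // ambiguous read base: not tallied
        }
      }
      ++pos;
    }
    if (!pending.empty() && pending_anchor >= 0) ++ins[{pending_anchor, pending}];
  }
  const int ni = ins.size();
  IntegerVector ipos(ni), icount(ni);
  CharacterVector iseq(ni);
  int k = 0;
  for (auto &kv : ins) {
    ipos[k] = kv.first.first; iseq[k] = kv.first.second; icount[k] = kv.second; ++k;
  }
  return List::create(_["counts"] = counts,
                      _["ins_pos"] = ipos, _["ins_seq"] = iseq,
                      _["ins_count"] = icount);
}

// Base carried by each read at each requested reference position
// ("" = not covered, "-" = deleted in the read).
// [[Rcpp::export]]
CharacterMatrix cpp_project_reads(IntegerVector starts,
                                  CharacterVector aligned_read,
                                  CharacterVector aligned_ref,
                                  IntegerVector positions) {
  const int nr = starts.size(), np = positions.size();
  CharacterMatrix out(nr, np);
  std::fill(out.begin(), out.end(), "");
  std::map<int, int> want;
  for (int p = 0; p < np; ++p) want[positions[p]] = p;
  for (int k = 0; k < nr; ++k) {
    std::string ar = as<std::string>(aligned_read[k]);
    std::string rr = as<std::string>(aligned_ref[k]);
    int pos = starts[k];
    for (size_t c = 0; c < ar.size(); ++c) {
      if (rr[c] == '-') continue;
      auto it = want.find(pos);
      if (it != want.end()) out(k, it->second) = std::string(1, ar[c]);
      ++pos;
    }
  }
  return out;
}
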