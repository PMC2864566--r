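#include <Rcpp.h>
using namespace Rcpp;

// Frameshift-aware local alignment of a protein segment against a DNA
// window, in the style of protein-to-genome aligners: a residue may consume
// 3 nt (codon match, substitution-scored), 1 or 2 nt (frameshift slip,
// fs_penalty), or 4 or 5 nt (codon match preceded by 1-2 slipped nt,
// substitution score minus fs_penalty). Residues may be deleted (affine
// protein gap) and whole in-frame codons inserted (affine DNA gap).
// Alignment across a stop codon is allowed at a fixed (negative)
// stop_score, so disruptions stay on the optimal path instead of breaking
// it.
//
// prot: 1-based indices into submat rows; dna: 0..3 (A,C,G,T; -1 for
// ambiguous); codon_aa: length-64 codon -> aa row index (0 = stop codon).
// Returns the optimal local score and the traceback operations.

static const double NEG = -1e18;

enum OpType { OP_MATCH = 1, OP_FS = 2, OP_PGAP = 3, OP_DGAP = 4 };

// [[Rcpp::export]]
List fs_align_cpp(IntegerVector prot, IntegerVector dna, NumericMatrix submat,
                  IntegerVector codon_aa, double gap_open, double gap_extend,
                  double fs_penalty, double stop_score) {
  const int m = prot.size(), n = dna.size();
  // state matrices: M (residue emitted), Ix (protein gap), Iy (DNA gap)
  std::vector<double> M((m + 1) * (n + 1), NEG), Ix(M), Iy(M);
  // traceback: packed move code per cell per state
  // move: 0 = start, 1..5 = emit consuming c nt from state q, 6 = pgap open,
  // 7 = pgap extend, 8 = dgap open, 9 = dgap extend; plus predecessor state
  std::vector<signed char> tbM((m + 1) * (n + 1), -1), tbMq(tbM),
      tbIx(tbM), tbIy(tbM);
  const int stride = n + 1;
  #define IDX(i, j) ((i) * stride + (j))

  for (int j = 0; j <= n; ++j) M[IDX(0, j)] = 0.0;  // local: free start
  for (int i = 0; i <= m; ++i) M[IDX(i, 0)] = (i == 0) ? 0.0 : NEG;
  M[IDX(0, 0)] = 0.0;

  double best = 0.0;
  int bi = 0, bj = 0, bq = 0;

  for (int i = 1; i <= m; ++i) {
    for (int j = 0; j <= n; ++j) {
      // --- M: emit residue i consuming c nt ending at j
      double mv = NEG;
      signed char mmove = -1, mq = 0;
      static const int cs[5] = {3, 1, 2, 4, 5};  // precedence order
      for (int k = 0; k < 5; ++k) {
        const int c = cs[k];
        if (j - c < 0) continue;
        double emit;
        if (c == 1 || c == 2) {
          emit = -fs_penalty;
        } else {
          const int d1 = dna[j - 3], d2 = dna[j - 2], d3 = dna[j - 1];
          if (d1 < 0 || d2 < 0 || d3 < 0)
            emit = -1.0;
          else {
            const int aa = codon_aa[16 * d1 + 4 * d2 + d3];
            emit = (aa == 0) ? stop_score
                             : submat(prot[i - 1] - 1, aa - 1);
          }
          if (c > 3) emit -= fs_penalty;
        }
        const double fromM = M[IDX(i - 1, j - c)],
                     fromX = Ix[IDX(i - 1, j - c)],
                     fromY = Iy[IDX(i - 1, j - c)];
        double pre = 0.0; int q = -1;         // fresh local start
        if (fromM >= pre) { pre = fromM; q = 0; }
        if (fromX > pre)  { pre = fromX; q = 1; }
        if (fromY > pre)  { pre = fromY; q = 2; }
        const double cand = pre + emit;
        if (cand > mv) { mv = cand; mmove = (signed char)c; mq = (signed char)q; }
      }
      M[IDX(i, j)] = mv;
      tbM[IDX(i, j)] = mmove;
      tbMq[IDX(i, j)] = mq;

      // --- Ix: residue i gapped (no DNA consumed)
      double xo = M[IDX(i - 1, j)] - gap_open;
      double xe = Ix[IDX(i - 1, j)] - gap_extend;
      if (xo >= xe) { Ix[IDX(i, j)] = xo; tbIx[IDX(i, j)] = 6; }
      else          { Ix[IDX(i, j)] = xe; tbIx[IDX(i, j)] = 7; }

      // --- Iy: in-frame DNA codon gapped (3 nt, no residue)
      if (j >= 3) {
        double yo = M[IDX(i, j - 3)] - gap_open;
        double ye = Iy[IDX(i, j - 3)] - gap_extend;
        if (yo >= ye) { Iy[IDX(i, j)] = yo; tbIy[IDX(i, j)] = 8; }
        else          { Iy[IDX(i, j)] = ye; tbIy[IDX(i, j)] = 9; }
      }

      if (M[IDX(i, j)] > best) { best = M[IDX(i, j)]; bi = i; bj = j; bq = 0; }
    }
  }

  // traceback from the best M cell
  std::vector<int> op_type, op_prot, op_dna_start, op_dna_len;
  int i = bi, j = bj, q = bq;
  while (i > 0 && best > 0.0) {
    if (q == 0) {
      const signed char mv = tbM[IDX(i, j)], pq = tbMq[IDX(i, j)];
      if (mv < 0) break;
      const int c = mv;
      op_type.push_back(c == 3 ? OP_MATCH : OP_FS);
      op_prot.push_back(i);
      op_dna_start.push_back(j - c + 1);  // 1-based
      op_dna_len.push_back(c);
      i -= 1; j -= c;
      if (pq < 0) break;          // fresh local start before this emit
      q = pq;
    } else if (q == 1) {
      op_type.push_back(OP_PGAP);
      op_prot.push_back(i);
      op_dna_start.push_back(j + 1);
      op_dna_len.push_back(0);
      const signed char mv = tbIx[IDX(i, j)];
      i -= 1;
      q = (mv == 6) ? 0 : 1;
    } else {
      op_type.push_back(OP_DGAP);
      op_prot.push_back(i);
      op_dna_start.push_back(j - 2);
      op_dna_len.push_back(3);
      const signed char mv = tbIy[IDX(i, j)];
      j -= 3;
      q = (mv == 8) ? 0 : 2;
    }
  }
  std::reverse(op_type.begin(), op_type.end());
  std::reverse(op_prot.begin(), op_prot.end());
  std::reverse(op_dna_start.begin(), op_dna_start.end());
  std::reverse(op_dna_len.begin(), op_dna_len.end());

  return List::create(
      _["score"] = best,
      _["ops"] = DataFrame::create(_["type"] = op_type, _["prot"] = op_prot,
                                   _["dna_start"] = op_dna_start,
                                   _["dna_len"] = op_dna_len));
}
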