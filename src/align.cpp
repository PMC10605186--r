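#include <Rcpp.h>
#include <cstring>
using namespace Rcpp;

// Local (Smith-Waterman) alignment with affine gaps and full traceback.
// Query and reference are plain ACGTN strings; N never matches.
// Returns 0-based half-open coordinates of the aligned blocks plus a
// CIGAR over the aligned region only (M/I/D; soft clips are implied by
// q_start / q_end). Ties are broken deterministically: the first maximal
// cell in row-major order wins, and traceback prefers diagonal, then
// deletion (gap in query), then insertion (gap in reference).
struct SwResult {
  double score;
  int q_start, q_end, r_start, r_end, nm;
  std::string cigar;
};

static SwResult sw_core(const std::string &q, const std::string &r,
                        double match, double mismatch, double gap_open,
                        double gap_extend);

// [[Rcpp::export]]
List sw_align_cpp(std::string q, std::string r,
                  double match = 1.0, double mismatch = -2.0,
                  double gap_open = -4.0, double gap_extend = -1.0) {
  SwResult res = sw_core(q, r, match, mismatch, gap_open, gap_extend);
  return List::create(_["score"] = res.score, _["q_start"] = res.q_start,
                      _["q_end"] = res.q_end, _["r_start"] = res.r_start,
                      _["r_end"] = res.r_end, _["cigar"] = res.cigar,
                      _["nm"] = res.nm);
}

// Batched variant of sw_align_cpp over parallel query/reference vectors.
// [[Rcpp::export]]
List sw_align_batch_cpp(CharacterVector qs, CharacterVector rs,
                        double match = 1.0, double mismatch = -2.0,
                        double gap_open = -4.0, double gap_extend = -1.0) {
  const int n = qs.size();
  NumericVector score(n);
  IntegerVector q_start(n), q_end(n), r_start(n), r_end(n), nm(n);
  CharacterVector cigar(n);
  for (int i = 0; i < n; ++i) {
    SwResult res = sw_core(as<std::string>(qs[i]), as<std::string>(rs[i]),
                           match, mismatch, gap_open, gap_extend);
    score[i] = res.score;
    q_start[i] = res.q_start; q_end[i] = res.q_end;
    r_start[i] = res.r_start; r_end[i] = res.r_end;
    nm[i] = res.nm; cigar[i] = res.cigar;
  }
  return List::create(_["score"] = score, _["q_start"] = q_start,
                      _["q_end"] = q_end, _["r_start"] = r_start,
                      _["r_end"] = r_end, _["cigar"] = cigar,
                      _["nm"] = nm);
}

static SwResult sw_core(const std::string &q, const std::string &r,
                        double match, double mismatch, double gap_open,
                        double gap_extend) {
  const int n = q.size(), m = r.size();
  if (n == 0 || m == 0) {
    return SwResult{0.0, 0, 0, 0, 0, 0, ""};
  }
  const int W = m + 1;
  std::vector<double> H((n + 1) * W, 0.0), E((n + 1) * W, R_NegInf),
      F((n + 1) * W, R_NegInf);
  // traceback codes for H: 0 stop, 1 diag, 2 from E (D op), 3 from F (I op)
  std::vector<unsigned char> tbH((n + 1) * W, 0), tbE((n + 1) * W, 0),
      tbF((n + 1) * W, 0);
  double best = 0.0;
  int bi = 0, bj = 0;
  for (int i = 1; i <= n; ++i) {
    const char qc = q[i - 1];
    for (int j = 1; j <= m; ++j) {
      const int id = i * W + j, up = (i - 1) * W + j, lf = id - 1,
                dg = up - 1;
      // E: gap in query (consumes reference) -> D
      double eo = H[lf] + gap_open, ee = E[lf] + gap_extend;
      if (eo >= ee) { E[id] = eo; tbE[id] = 0; } else { E[id] = ee; tbE[id] = 1; }
      // F: gap in reference (consumes query) -> I
      double fo = H[up] + gap_open, fe = F[up] + gap_extend;
      if (fo >= fe) { F[id] = fo; tbF[id] = 0; } else { F[id] = fe; tbF[id] = 1; }
      const char rc = r[j - 1];
      const bool ok = (qc == rc) && qc != 'N' && qc != 'n';
      double dsc = H[dg] + (ok ? match : mismatch);
      double h = 0.0; unsigned char tb = 0;
      if (dsc > h) { h = dsc; tb = 1; }
      if (E[id] > h) { h = E[id]; tb = 2; }
      if (F[id] > h) { h = F[id]; tb = 3; }
      H[id] = h; tbH[id] = tb;
      if (h > best) { best = h; bi = i; bj = j; }
    }
  }
  // traceback
  std::string ops;
  int i = bi, j = bj, nm = 0;
  while (i > 0 && j > 0 && tbH[i * W + j] != 0) {
    const int id = i * W + j;
    const unsigned char tb = tbH[id];
    if (tb == 1) {
      ops.push_back('M');
      const bool ok = (q[i - 1] == r[j - 1]) && q[i - 1] != 'N';
      if (!ok) ++nm;
      --i; --j;
    } else if (tb == 2) {
      // run of D ops
      while (true) {
        ops.push_back('D'); ++nm;
        const unsigned char ext = tbE[i * W + j];
        --j;
        if (!ext) break;
      }
    } else {
      while (true) {
        ops.push_back('I'); ++nm;
        const unsigned char ext = tbF[i * W + j];
        --i;
        if (!ext) break;
      }
    }
  }
  std::reverse(ops.begin(), ops.end());
  // run-length encode
  std::string cigar;
  for (size_t k = 0; k < ops.size();) {
    size_t k2 = k;
    while (k2 < ops.size() && ops[k2] == ops[k]) ++k2;
    cigar += std::to_string(k2 - k);
    cigar.push_back(ops[k]);
    k = k2;
  }
  return SwResult{best, i, bi, j, bj, nm, cigar};
}

// Best primer for each read prefix by Hamming distance.
// Returns an n x 3 integer matrix: best primer index (1-based, 0 if none
// within max_mm), mismatch count of the best, and how many primers tie at
// that count (ties -> ambiguous assignment).
// [[Rcpp::export]]
IntegerMatrix primer_prefix_mm_cpp(CharacterVector reads,
                                   CharacterVector primers, int max_mm) {
  const int n = reads.size(), np = primers.size();
  std::vector<std::string> ps(np);
  for (int p = 0; p < np; ++p) ps[p] = as<std::string>(primers[p]);
  IntegerMatrix out(n, 3);
  for (int i = 0; i < n; ++i) {
    const char *rd = CHAR(STRING_ELT(reads, i));
    const int rl = std::strlen(rd);
    int bestmm = max_mm + 1, bestp = 0, nbest = 0;
    for (int p = 0; p < np; ++p) {
      const std::string &pr = ps[p];
      const int pl = pr.size();
      if (pl > rl) continue;
      int mm = 0;
      for (int k = 0; k < pl && mm <= max_mm; ++k)
        if (rd[k] != pr[k]) ++mm;
      if (mm <= max_mm) {
        if (mm < bestmm) { bestmm = mm; bestp = p + 1; nbest = 1; }
        else if (mm == bestmm) ++nbest;
      }
    }
    out(i, 0) = (bestmm <= max_mm) ? bestp : 0;
    out(i, 1) = (bestmm <= max_mm) ? bestmm : NA_INTEGER;
    out(i, 2) = nbest;
  }
  return out;
}

// Expand a batch of alignment records into per-position events.
// For every aligned M column emits (record, ref_pos, allele, qual);
// insertions emit a "+SEQ" token anchored at the reference position that
// follows them; deletions emit a "-" token at every deleted position.
// Coordinates are 0-based. cigars cover the aligned region only.
// [[Rcpp::export]]
List aligned_events_cpp(CharacterVector seqs, CharacterVector quals,
                        IntegerVector q_starts, IntegerVector r_starts,
                        CharacterVector cigars) {
  const int n = seqs.size();
  std::vector<int> rec, pos, qv;
  std::vector<std::string> allele;
  for (int i = 0; i < n; ++i) {
    const char *sq = CHAR(STRING_ELT(seqs, i));
    const char *ql = CHAR(STRING_ELT(quals, i));
    std::string cg = as<std::string>(cigars[i]);
    int qp = q_starts[i], rp = r_starts[i];
    size_t k = 0;
    while (k < cg.size()) {
      int len = 0;
      size_t k2 = k;
      while (k2 < cg.size() && cg[k2] >= '0' && cg[k2] <= '9') {
        len = len * 10 + (cg[k2] - '0');
        ++k2;
      }
      const char op = cg[k2];
      k = k2 + 1;
      if (op == 'M') {
        for (int t = 0; t < len; ++t) {
          rec.push_back(i + 1);
          pos.push_back(rp + t);
          allele.push_back(std::string(1, sq[qp + t]));
          qv.push_back((int)ql[qp + t] - 33);
        }
        qp += len; rp += len;
      } else if (op == 'I') {
        std::string ins = "+";
        for (int t = 0; t < len; ++t) ins.push_back(sq[qp + t]);
        rec.push_back(i + 1);
        pos.push_back(rp);
        allele.push_back(ins);
        qv.push_back((int)ql[qp] - 33);
        qp += len;
      } else if (op == 'D') {
        for (int t = 0; t < len; ++t) {
          rec.push_back(i + 1);
          pos.push_back(rp + t);
          allele.push_back("-");
          qv.push_back((int)ql[qp > 0 ? qp - 1 : 0] - 33);
        }
        rp += len;
      } else {
        stop("unsupported CIGAR op in aligned_events_cpp");
      }
    }
  }
  return List::create(_["rec"] = wrap(rec), _["pos"] = wrap(pos),
                      _["allele"] = wrap(allele), _["qual"] = wrap(qv));
}
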