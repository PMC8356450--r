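#include <Rcpp.h>
#include <algorithm>
#include <cstring>
using namespace Rcpp;

// Haplotypes are stored as a raw matrix with one column per haplotype and one
// row per locus (0x00/0x01 allele codes), loci sorted by (chromosome, cM
// position). Individual i (1-based) owns columns 2i-1 and 2i.

// Copy one meiotic product of the two parental haplotype columns `h1`,`h2`
// into `out`. Crossovers are Poisson(length/100 cM) per chromosome, uniform
// positions, no interference; a fresh random starting haplotype per
// chromosome gives independent assortment. Uses R's RNG.
static void gamete(const Rbyte* h1, const Rbyte* h2, Rbyte* out,
                   const int* cstart, const int* cend, int nchrom,
                   const double* pos, const double* clen) {
  for (int c = 0; c < nchrom; ++c) {
    const int lo = cstart[c], hi = cend[c];     // [lo, hi) locus range
    const int nloc = hi - lo;
    if (nloc <= 0) continue;
    int k = (int) R::rpois(clen[c] / 100.0);
    int cur = (unif_rand() < 0.5) ? 0 : 1;
    if (k == 0) {
      std::memcpy(out + lo, (cur ? h2 : h1) + lo, (size_t) nloc);
      continue;
    }
    double xpos[64];
    if (k > 64) k = 64;                          // Poisson(1): never in practice
    for (int j = 0; j < k; ++j) xpos[j] = unif_rand() * clen[c];
    std::sort(xpos, xpos + k);
    int seg = lo;
    for (int j = 0; j < k; ++j) {
      const double* p = std::lower_bound(pos + seg, pos + hi, xpos[j]);
      int brk = (int) (p - pos);
      if (brk > seg)
        std::memcpy(out + seg, (cur ? h2 : h1) + seg, (size_t) (brk - seg));
      seg = brk;
      cur = 1 - cur;
    }
    if (hi > seg)
      std::memcpy(out + seg, (cur ? h2 : h1) + seg, (size_t) (hi - seg));
  }
}

// [[Rcpp::export]]
RawMatrix cpp_random_haplotypes(int nloci, int nhap) {
  RawMatrix out(nloci, nhap);
  Rbyte* p = RAW(out);
  R_xlen_t n = (R_xlen_t) nloci * nhap;
  for (R_xlen_t i = 0; i < n; ++i) p[i] = (unif_rand() < 0.5) ? 1 : 0;
  return out;
}

// One generation of meioses: offspring o gets a paternal gamete from
// individual sire[o] and a maternal gamete from dam[o] (1-based columns into
// `haps`). RNG order: offspring in order, paternal gamete then maternal.
// [[Rcpp::export]]
RawMatrix cpp_drop_generation(RawMatrix haps, IntegerVector sire,
                              IntegerVector dam, IntegerVector chrom_start,
                              IntegerVector chrom_end, NumericVector pos,
                              NumericVector chrom_len) {
  const int L = haps.nrow();
  const int noff = sire.size();
  if (dam.size() != noff) stop("sire/dam length mismatch");
  RawMatrix out(L, 2 * noff);
  const Rbyte* hp = RAW(haps);
  Rbyte* op = RAW(out);
  const int nchrom = chrom_start.size();
  for (int o = 0; o < noff; ++o) {
    int s = sire[o], d = dam[o];
    if (s < 1 || d < 1 || 2 * s > haps.ncol() || 2 * d > haps.ncol())
      stop("parent index out of range");
    gamete(hp + (R_xlen_t) L * (2 * s - 2), hp + (R_xlen_t) L * (2 * s - 1),
           op + (R_xlen_t) L * (2 * o), chrom_start.begin(), chrom_end.begin(),
           nchrom, pos.begin(), chrom_len.begin());
    gamete(hp + (R_xlen_t) L * (2 * d - 2), hp + (R_xlen_t) L * (2 * d - 1),
           op + (R_xlen_t) L * (2 * o + 1), chrom_start.begin(),
           chrom_end.begin(), nchrom, pos.begin(), chrom_len.begin());
  }
  return out;
}

// As cpp_drop_generation, but writes into the first 2*noff columns of the
// preallocated buffer `out` (same locus layout) and returns nothing. Lets
// the caller alternate two buffers across many generations instead of
// allocating one matrix per generation.
// [[Rcpp::export]]
void cpp_drop_generation_into(RawMatrix haps, int nparent, IntegerVector sire,
                              IntegerVector dam, IntegerVector chrom_start,
                              IntegerVector chrom_end, NumericVector pos,
                              NumericVector chrom_len, RawMatrix out) {
  const int L = haps.nrow();
  const int noff = sire.size();
  if (out.nrow() != L) stop("buffer locus dimension mismatch");
  if (out.ncol() < 2 * noff) stop("buffer too small for offspring");
  if (dam.size() != noff) stop("sire/dam length mismatch");
  const Rbyte* hp = RAW(haps);
  Rbyte* op = RAW(out);
  const int nchrom = chrom_start.size();
  for (int o = 0; o < noff; ++o) {
    int s = sire[o], d = dam[o];
    if (s < 1 || d < 1 || s > nparent || d > nparent ||
        2 * s > haps.ncol() || 2 * d > haps.ncol())
      stop("parent index out of range");
    gamete(hp + (R_xlen_t) L * (2 * s - 2), hp + (R_xlen_t) L * (2 * s - 1),
           op + (R_xlen_t) L * (2 * o), chrom_start.begin(), chrom_end.begin(),
           nchrom, pos.begin(), chrom_len.begin());
    gamete(hp + (R_xlen_t) L * (2 * d - 2), hp + (R_xlen_t) L * (2 * d - 1),
           op + (R_xlen_t) L * (2 * o + 1), chrom_start.begin(),
           chrom_end.begin(), nchrom, pos.begin(), chrom_len.begin());
  }
}

// Fill the first `nhap` columns of `out` with Bernoulli(0.5) alleles.
// [[Rcpp::export]]
void cpp_fill_random(RawMatrix out, int nhap) {
  if (nhap > out.ncol()) stop("buffer too small");
  Rbyte* p = RAW(out);
  R_xlen_t n = (R_xlen_t) out.nrow() * nhap;
  for (R_xlen_t i = 0; i < n; ++i) p[i] = (unif_rand() < 0.5) ? 1 : 0;
}

// `ngam` independent gametes from one parent (columns 2*parent-1, 2*parent).
// [[Rcpp::export]]
RawMatrix cpp_gametes(RawMatrix haps, int parent, int ngam,
                      IntegerVector chrom_start, IntegerVector chrom_end,
                      NumericVector pos, NumericVector chrom_len) {
  const int L = haps.nrow();
  if (parent < 1 || 2 * parent > haps.ncol()) stop("parent index out of range");
  RawMatrix out(L, ngam);
  const Rbyte* h1 = RAW(haps) + (R_xlen_t) L * (2 * parent - 2);
  const Rbyte* h2 = RAW(haps) + (R_xlen_t) L * (2 * parent - 1);
  for (int g = 0; g < ngam; ++g)
    gamete(h1, h2, RAW(out) + (R_xlen_t) L * g, chrom_start.begin(),
           chrom_end.begin(), chrom_start.size(), pos.begin(),
           chrom_len.begin());
  return out;
}

// Numerator relationship matrix by the tabular method. Pedigree must be
// sorted parents-before-offspring; 0 codes an unknown (founder) parent.
// [[Rcpp::export]]
NumericMatrix cpp_tabular_A(IntegerVector sire, IntegerVector dam) {
  const int n = sire.size();
  NumericMatrix A(n, n);
  for (int i = 0; i < n; ++i) {
    const int s = sire[i], d = dam[i];
    if (s > i || d > i) stop("pedigree not sorted: parent after offspring");
    for (int j = 0; j < i; ++j) {
      double a = 0.0;
      if (s > 0) a += 0.5 * A(j, s - 1);
      if (d > 0) a += 0.5 * A(j, d - 1);
      A(j, i) = A(i, j) = a;
    }
    A(i, i) = 1.0 + ((s > 0 && d > 0) ? 0.5 * A(s - 1, d - 1) : 0.0);
  }
  return A;
}

// Genotype dosages (0/1/2) for selected individuals x selected loci.
// [[Rcpp::export]]
NumericMatrix cpp_dosage(RawMatrix haps, IntegerVector loci,
                         IntegerVector ind) {
  const int L = haps.nrow();
  const int n = ind.size(), m = loci.size();
  NumericMatrix out(n, m);
  const Rbyte* hp = RAW(haps);
  for (int j = 0; j < m; ++j) {
    const int l = loci[j] - 1;
    if (l < 0 || l >= L) stop("locus index out of range");
    for (int i = 0; i < n; ++i) {
      const R_xlen_t c = (R_xlen_t) L * (2 * ind[i] - 2);
      out(i, j) = (double) hp[c + l] + (double) hp[c + L + l];
    }
  }
  return out;
}

// Allele frequency (mean of the 0/1 allele code) per locus over all columns.
// [[Rcpp::export]]
NumericVector cpp_allele_freq(RawMatrix haps, IntegerVector loci) {
  const int L = haps.nrow(), H = haps.ncol();
  const int m = loci.size();
  NumericVector out(m);
  const Rbyte* hp = RAW(haps);
  for (int j = 0; j < m; ++j) {
    const int l = loci[j] - 1;
    if (l < 0 || l >= L) stop("locus index out of range");
    long s = 0;
    for (int h = 0; h < H; ++h) s += hp[(R_xlen_t) L * h + l];
    out[j] = (double) s / H;
  }
  return out;
}

// Squared correlation of allele states across haplotypes for locus pairs
// (gametic-phase r^2). NaN where either locus is monomorphic.
// [[Rcpp::export]]
NumericVector cpp_pair_r2(RawMatrix haps, IntegerVector lociA,
                          IntegerVector lociB) {
  const int L = haps.nrow(), H = haps.ncol();
  const int m = lociA.size();
  if (lociB.size() != m) stop("locus vectors differ in length");
  NumericVector out(m);
  const Rbyte* hp = RAW(haps);
  for (int j = 0; j < m; ++j) {
    const int a = lociA[j] - 1, b = lociB[j] - 1;
    if (a < 0 || a >= L || b < 0 || b >= L) stop("locus index out of range");
    long sa = 0, sb = 0, sab = 0;
    for (int h = 0; h < H; ++h) {
      const Rbyte* col = hp + (R_xlen_t) L * h;
      sa += col[a];
      sb += col[b];
      sab += col[a] & col[b];
    }
    const double pa = (double) sa / H, pb = (double) sb / H;
    const double D = (double) sab / H - pa * pb;
    const double den = pa * (1 - pa) * pb * (1 - pb);
    out[j] = den > 0 ? D * D / den : R_NaN;
  }
  return out;
}
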