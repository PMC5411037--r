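// Backward-time coalescent machinery: two-population divergence
// genealogies, stepwise-mutation microsatellites, K2P sequence evolution,
// and the fixed summary-statistic vector used for ABC. All randomness
// comes from R's RNG so set.seed() in R governs reproducibility.

#include <Rcpp.h>
#include <vector>
#include <map>
#include <cmath>
using namespace Rcpp;

struct Genealogy {
  // tips 0..n-1, internal nodes n..2n-2 in coalescence order (parents
  // always have larger index than children); times in generations.
  std::vector<int> parent;
  std::vector<double> time;
  int n;
};

static void coalescePair(std::vector<int> &act, std::vector<int> &parent,
                         std::vector<double> &time, int &nextNode,
                         double cur) {
  int k = act.size();
  int i = (int)(unif_rand() * k); if (i == k) i--;
  int j = (int)(unif_rand() * (k - 1)); if (j == k - 1) j--;
  if (j >= i) j++;
  int a = act[i], b = act[j];
  parent[a] = nextNode; parent[b] = nextNode;
  time[nextNode] = cur;
  if (i > j) std::swap(i, j);
  act[i] = nextNode;
  act.erase(act.begin() + j);
  nextNode++;
}

// Two demes with gene-copy counts (g1a, g2a) on [0, t1), (g1b, g2b) on
// [t1, t), merging into an ancestral pool of ganc copies at t. Pairwise
// coalescence rate within a deme of g copies is 1/g per generation.
static Genealogy simGenealogy(int n1, int n2, double g1a, double g2a,
                              double g1b, double g2b, double t1, double t,
                              double ganc) {
  int n = n1 + n2;
  Genealogy G;
  G.n = n;
  G.parent.assign(2 * n - 1, -1);
  G.time.assign(2 * n - 1, 0.0);
  std::vector<int> d1, d2;
  for (int i = 0; i < n1; i++) d1.push_back(i);
  for (int i = 0; i < n2; i++) d2.push_back(n1 + i);
  int nextNode = n;
  double cur = 0.0;
  while (cur < t) {
    double s1 = (cur < t1) ? g1a : g1b;
    double s2 = (cur < t1) ? g2a : g2b;
    double bound = (cur < t1) ? std::min(t1, t) : t;
    double k1 = d1.size(), k2 = d2.size();
    double r1 = (k1 > 1) ? k1 * (k1 - 1) / 2.0 / s1 : 0.0;
    double r2 = (k2 > 1) ? k2 * (k2 - 1) / 2.0 / s2 : 0.0;
    double rate = r1 + r2;
    if (rate <= 0) { cur = bound; continue; }
    double dt = exp_rand() / rate;
    if (cur + dt >= bound) { cur = bound; continue; }
    cur += dt;
    if (unif_rand() * rate < r1)
      coalescePair(d1, G.parent, G.time, nextNode, cur);
    else
      coalescePair(d2, G.parent, G.time, nextNode, cur);
  }
  std::vector<int> act = d1;
  act.insert(act.end(), d2.begin(), d2.end());
  while (act.size() > 1) {
    double k = act.size();
    double rate = k * (k - 1) / 2.0 / ganc;
    cur += exp_rand() / rate;
    coalescePair(act, G.parent, G.time, nextNode, cur);
  }
  return G;
}

// Reflect a microsatellite allele code into [lo, hi].
static int foldAllele(long x, int lo, int hi) {
  long w = hi - lo;
  long y = (x - lo) % (2 * w);
  if (y < 0) y += 2 * w;
  if (y > w) y = 2 * w - y;
  return (int)(lo + y);
}

// Drop stepwise mutations on a genealogy; model 0 = strict SMM, 1 = TPM
// (multi-step sizes geometric with parameter geomQ, sign symmetric).
static std::vector<int> msatFromGenealogy(const Genealogy &G, double mu,
                                          int rootAllele, int model,
                                          double pStep, double geomQ,
                                          int lo, int hi) {
  int total = 2 * G.n - 1;
  std::vector<long> allele(total);
  allele[total - 1] = rootAllele;
  for (int i = total - 2; i >= 0; i--) {
    double len = G.time[G.parent[i]] - G.time[i];
    int k = (int)R::rpois(mu * len);
    long net = 0;
    if (model == 0) {
      int up = (int)R::rbinom(k, 0.5);
      net = 2L * up - k;
    } else {
      for (int m = 0; m < k; m++) {
        int step = 1;
        if (unif_rand() > pStep) step = (int)R::rgeom(geomQ) + 1;
        net += (unif_rand() < 0.5) ? step : -step;
      }
    }
    allele[i] = allele[G.parent[i]] + net;
  }
  std::vector<int> out(G.n);
  for (int i = 0; i < G.n; i++) out[i] = foldAllele(allele[i], lo, hi);
  return out;
}

// K2P sequence evolution: per-branch substitution count Poisson(rate * L *
// len); each substitution hits a uniform site, transition with probability
// tsRatio/(tsRatio + 1). Bases coded 0=A,1=C,2=G,3=T.
static IntegerMatrix mtFromGenealogy(const Genealogy &G, double rate,
                                     int L, double tsRatio) {
  int total = 2 * G.n - 1;
  double pTs = tsRatio / (tsRatio + 1.0);
  std::vector<std::vector<unsigned char> > seq(total);
  seq[total - 1].resize(L);
  for (int j = 0; j < L; j++)
    seq[total - 1][j] = (unsigned char)(unif_rand() * 4) & 3;
  for (int i = total - 2; i >= 0; i--) {
    seq[i] = seq[G.parent[i]];
    double len = G.time[G.parent[i]] - G.time[i];
    int k = (int)R::rpois(rate * L * len);
    for (int m = 0; m < k; m++) {
      int site = (int)(unif_rand() * L); if (site == L) site--;
      unsigned char b = seq[i][site];
      unsigned char nb;
      if (unif_rand() < pTs) {
        // transitions: A<->G (0<->2), C<->T (1<->3)
        nb = b ^ 2;
      } else {
        // one of the two transversion partners
        unsigned char opts[2];
        int c = 0;
        for (unsigned char o = 0; o < 4; o++)
          if (o != b && o != (b ^ 2)) opts[c++] = o;
        nb = opts[unif_rand() < 0.5 ? 0 : 1];
      }
      seq[i][site] = nb;
    }
    // free parent storage when both children done is skipped for clarity
  }
  IntegerMatrix out(G.n, L);
  for (int i = 0; i < G.n; i++)
    for (int j = 0; j < L; j++) out(i, j) = seq[i][j];
  return out;
}

// ---- summary statistics ------------------------------------------------

struct MsatPopStats { double A, He, Var; };

static MsatPopStats msatPopStats(const std::vector<int> &genes) {
  MsatPopStats s;
  int n = genes.size();
  std::map<int, int> cnt;
  double mean = 0;
  for (int g : genes) { cnt[g]++; mean += g; }
  mean /= n;
  double sump2 = 0, var = 0;
  for (auto &kv : cnt) {
    double p = (double)kv.second / n;
    sump2 += p * p;
  }
  for (int g : genes) var += (g - mean) * (g - mean);
  s.A = cnt.size();
  s.He = (n > 1) ? (double)n / (n - 1) * (1.0 - sump2) : NA_REAL;
  s.Var = (n > 1) ? var / (n - 1) : NA_REAL;
  return s;
}

// Weir-Cockerham theta summed over alleles and loci for two populations.
static double wcTheta(const IntegerMatrix &msat, int n1, int L) {
  // msat: n x 2L, columns 2l, 2l+1 are the two alleles of locus l
  int n = msat.nrow();
  double A = 0, B = 0, C = 0;
  for (int l = 0; l < L; l++) {
    std::map<int, int> codes;
    for (int i = 0; i < n; i++) {
      codes[msat(i, 2 * l)] = 1; codes[msat(i, 2 * l + 1)] = 1;
    }
    if (codes.size() < 2) continue;
    double ni[2] = {(double)n1, (double)(n - n1)};
    double r = 2, nbar = (ni[0] + ni[1]) / 2.0;
    double nc = (r * nbar - (ni[0] * ni[0] + ni[1] * ni[1]) / (r * nbar))
                / (r - 1);
    for (auto &kv : codes) {
      int al = kv.first;
      double p[2] = {0, 0}, h[2] = {0, 0};
      for (int i = 0; i < n; i++) {
        int pop = (i < n1) ? 0 : 1;
        int a = msat(i, 2 * l), b = msat(i, 2 * l + 1);
        p[pop] += (a == al) + (b == al);
        h[pop] += ((a == al) != (b == al));
      }
      for (int q = 0; q < 2; q++) { p[q] /= 2 * ni[q]; h[q] /= ni[q]; }
      double pbar = (ni[0] * p[0] + ni[1] * p[1]) / (r * nbar);
      double s2 = (ni[0] * (p[0] - pbar) * (p[0] - pbar)
                 + ni[1] * (p[1] - pbar) * (p[1] - pbar)) / ((r - 1) * nbar);
      double hbar = (ni[0] * h[0] + ni[1] * h[1]) / (r * nbar);
      A += (nbar / nc) * (s2 - (pbar * (1 - pbar) - (r - 1) / r * s2
                                - hbar / 4) / (nbar - 1));
      B += (nbar / (nbar - 1)) * (pbar * (1 - pbar) - (r - 1) / r * s2
                                  - (2 * nbar - 1) / (4 * nbar) * hbar);
      C += hbar / 2;
    }
  }
  double denom = A + B + C;
  if (denom == 0) return NA_REAL;
  return A / denom;
}

static double tajD(int n, int S, double pi) {
  if (n < 4 || S < 1) return NA_REAL;
  double a1 = 0, a2 = 0;
  for (int i = 1; i < n; i++) { a1 += 1.0 / i; a2 += 1.0 / ((double)i * i); }
  double b1 = (n + 1.0) / (3.0 * (n - 1));
  double b2 = 2.0 * (n * (double)n + n + 3) / (9.0 * n * (n - 1.0));
  double c1 = b1 - 1 / a1;
  double c2 = b2 - (n + 2.0) / (a1 * n) + a2 / (a1 * a1);
  double e1 = c1 / a1, e2 = c2 / (a1 * a1 + a2);
  return (pi - S / a1) / std::sqrt(e1 * S + e2 * (double)S * (S - 1));
}

// [[Rcpp::export(name = ".cppSummaryStats")]]
NumericVector cppSummaryStats(IntegerMatrix msat, int n1,
                              IntegerMatrix mt, int m1) {
  int n = msat.nrow();
  int L = msat.ncol() / 2;
  int m = mt.nrow();
  int Lmt = mt.ncol();
  NumericVector out(18);
  // microsatellite per-pop means over loci
  double A[2] = {0, 0}, He[2] = {0, 0}, Var[2] = {0, 0};
  for (int l = 0; l < L; l++) {
    for (int pop = 0; pop < 2; pop++) {
      std::vector<int> genes;
      int from = (pop == 0) ? 0 : n1, to = (pop == 0) ? n1 : n;
      for (int i = from; i < to; i++) {
        genes.push_back(msat(i, 2 * l));
        genes.push_back(msat(i, 2 * l + 1));
      }
      MsatPopStats s = msatPopStats(genes);
      A[pop] += s.A; He[pop] += s.He; Var[pop] += s.Var;
    }
  }
  out[0] = A[0] / L; out[1] = A[1] / L;
  out[2] = He[0] / L; out[3] = He[1] / L;
  out[4] = Var[0] / L; out[5] = Var[1] / L;
  // mtDNA: restrict to variable sites (haplotype identity and all
  // difference counts are unchanged), then collapse to haplotypes
  std::vector<int> varSites;
  for (int j = 0; j < Lmt; j++) {
    int first = mt(0, j);
    for (int i = 1; i < m; i++)
      if (mt(i, j) != first) { varSites.push_back(j); break; }
  }
  int V = varSites.size();
  std::map<std::vector<int>, std::pair<int, int> > hap; // counts per pop
  for (int i = 0; i < m; i++) {
    std::vector<int> s(V);
    for (int j = 0; j < V; j++) s[j] = mt(i, varSites[j]);
    if (i < m1) hap[s].first++; else hap[s].second++;
  }
  int H = hap.size();
  std::vector<std::vector<int> > hseq;
  std::vector<int> c1, c2;
  for (auto &kv : hap) {
    hseq.push_back(kv.first);
    c1.push_back(kv.second.first);
    c2.push_back(kv.second.second);
  }
  // pairwise differences between haplotypes
  NumericMatrix hd(H, H);
  for (int a = 0; a < H; a++)
    for (int b = a + 1; b < H; b++) {
      int d = 0;
      for (int j = 0; j < V; j++) if (hseq[a][j] != hseq[b][j]) d++;
      hd(a, b) = hd(b, a) = d;
    }
  int shared = 0;
  for (int a = 0; a < H; a++) if (c1[a] > 0 && c2[a] > 0) shared++;
  double hn[2], hdv[2], pi[2], td[2];
  for (int pop = 0; pop < 2; pop++) {
    std::vector<int> *cc = (pop == 0) ? &c1 : &c2;
    int np = 0, nh = 0;
    for (int a = 0; a < H; a++) { np += (*cc)[a]; nh += ((*cc)[a] > 0); }
    hn[pop] = nh;
    double sump2 = 0, sumd = 0;
    int S = 0;
    for (int a = 0; a < H; a++) {
      double p = (double)(*cc)[a] / np;
      sump2 += p * p;
      for (int b = a + 1; b < H; b++)
        sumd += (double)(*cc)[a] * (*cc)[b] * hd(a, b);
    }
    hdv[pop] = (np > 1) ? (double)np / (np - 1) * (1 - sump2) : NA_REAL;
    pi[pop] = (np > 1) ? sumd / (np * (np - 1.0) / 2.0) : NA_REAL;
    // segregating sites within pop
    for (int j = 0; j < V; j++) {
      int seen = -1; bool var = false;
      for (int a = 0; a < H && !var; a++) {
        if ((*cc)[a] == 0) continue;
        if (seen < 0) seen = hseq[a][j];
        else if (hseq[a][j] != seen) var = true;
      }
      if (var) S++;
    }
    td[pop] = tajD(np, S, pi[pop]);
  }
  out[6] = hn[0]; out[7] = hn[1];
  out[8] = hdv[0]; out[9] = hdv[1];
  out[10] = pi[0]; out[11] = pi[1];
  out[12] = td[0]; out[13] = td[1];
  out[14] = wcTheta(msat, n1, L);
  // PhiST from haplotype counts and distances (two-level AMOVA)
  {
    int N = m, P = 2;
    double np[2] = {(double)m1, (double)(m - m1)};
    double ssT = 0, ssW = 0;
    double sumAll = 0, sumW[2] = {0, 0};
    for (int a = 0; a < H; a++)
      for (int b = a; b < H; b++) {
        double d = hd(a, b);
        if (d == 0) continue;
        double tot = (double)(c1[a] + c2[a]) * (c1[b] + c2[b]);
        if (a == b) tot = 0;
        sumAll += tot * d;
        sumW[0] += (double)c1[a] * ((a == b) ? 0 : c1[b]) * d;
        sumW[1] += (double)c2[a] * ((a == b) ? 0 : c2[b]) * d;
      }
    ssT = sumAll / N;
    ssW = sumW[0] / np[0] + sumW[1] / np[1];
    double s2w = ssW / (N - P);
    double nprime = (N - (np[0] * np[0] + np[1] * np[1]) / N) / (P - 1);
    double s2a = ((ssT - ssW) / (P - 1) - s2w) / nprime;
    out[15] = (s2a + s2w != 0) ? s2a / (s2a + s2w) : NA_REAL;
  }
  // shared-allele distance: 1 - mean over loci of sum_a min(p1a, p2a)
  {
    double acc = 0;
    for (int l = 0; l < L; l++) {
      std::map<int, std::pair<int, int> > cnts;
      for (int i = 0; i < n; i++) {
        for (int q = 0; q < 2; q++) {
          int al = msat(i, 2 * l + q);
          if (i < n1) cnts[al].first++; else cnts[al].second++;
        }
      }
      double s = 0;
      for (auto &kv : cnts) {
        double p1 = (double)kv.second.first / (2.0 * n1);
        double p2 = (double)kv.second.second / (2.0 * (n - n1));
        s += std::min(p1, p2);
      }
      acc += 1.0 - s;
    }
    out[17 - 1] = acc / L; // DAS at index 16
  }
  out[17] = shared;
  return out;
}

// [[Rcpp::export(name = ".cppSimulateScenario")]]
List cppSimulateScenario(double NATL, double NMED, double NbATL,
                         double NbMED, double t, double t1, double Nanc,
                         NumericVector muMsat, double muMt,
                         int n1, int n2, int m1, int m2,
                         int seqLen, double tsRatio,
                         int msatModel, double pStep, double geomQ,
                         bool returnSample) {
  int L = muMsat.size();
  int n = n1 + n2;
  IntegerMatrix msat(n, 2 * L);
  for (int l = 0; l < L; l++) {
    Genealogy G1 = simGenealogy(2 * n1, 2 * n2, 2 * NATL, 2 * NMED,
                                2 * NbATL, 2 * NbMED, t1, t, 2 * Nanc);
    std::vector<int> al = msatFromGenealogy(G1, muMsat[l], 175, msatModel,
                                            pStep, geomQ, 50, 300);
    // genes 0..2n1-1 are deme 1; pair consecutive genes into individuals
    for (int i = 0; i < n; i++) {
      msat(i, 2 * l) = al[2 * i];
      msat(i, 2 * l + 1) = al[2 * i + 1];
    }
  }
  Genealogy Gm = simGenealogy(m1, m2, NATL / 4.0, NMED / 4.0,
                              NbATL / 4.0, NbMED / 4.0, t1, t, Nanc / 4.0);
  IntegerMatrix mt = mtFromGenealogy(Gm, muMt, seqLen, tsRatio);
  NumericVector stats = cppSummaryStats(msat, n1, mt, m1);
  if (returnSample)
    return List::create(_["stats"] = stats, _["msat"] = msat,
                        _["mt"] = mt);
  return List::create(_["stats"] = stats);
}

// Mean TMRCA (generations) of a single deme sample: used for calibration
// checks against coalescent theory.
// [[Rcpp::export(name = ".cppMeanTmrca")]]
double cppMeanTmrca(int n, double copies, int reps) {
  double acc = 0;
  for (int r = 0; r < reps; r++) {
    Genealogy G = simGenealogy(n, 0, copies, copies, copies, copies,
                               1e18, 2e18, copies);
    acc += G.time[2 * n - 2];
  }
  return acc / reps;
}

// Equilibrium single-population microsatellite coalescent: returns one
// row (allele count k, unbiased He) per replicate. theta = 2 * copies *
// mu; mutations at rate theta/2 per coalescent time unit.
// [[Rcpp::export(name = ".cppSimEqMsat")]]
NumericMatrix cppSimEqMsat(int n, double theta, int reps, int model,
                           double pStep, double geomQ) {
  NumericMatrix out(reps, 2);
  for (int r = 0; r < reps; r++) {
    // coalescent in units of copies generations: rate C(k,2), mutations
    // theta/2 per unit per lineage
    Genealogy G = simGenealogy(n, 0, 1.0, 1.0, 1.0, 1.0, 1e18, 2e18, 1.0);
    std::vector<int> al = msatFromGenealogy(G, theta / 2.0, 0, model,
                                            pStep, geomQ, -100000, 100000);
    std::map<int, int> cnt;
    for (int v : al) cnt[v]++;
    double sump2 = 0;
    for (auto &kv : cnt) {
      double p = (double)kv.second / n;
      sump2 += p * p;
    }
    out(r, 0) = cnt.size();
    out(r, 1) = (double)n / (n - 1) * (1 - sump2);
  }
  return out;
}
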