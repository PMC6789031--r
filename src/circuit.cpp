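// Layered LIF microcircuit: network construction (random synapse assignment
// with replacement, normal weights/delays) and trial simulation with exact
// exponential integration of the linear membrane/synapse equations.
//
// The network is held in an external pointer so the ~10^7 synapses of a
// desk-scale build never cross into R.
#include <Rcpp.h>
#include <cstdint>
#include <cmath>
#include <vector>
using namespace Rcpp;

// Deterministic RNG independent of stdlib distribution implementations:
// splitmix-seeded xoshiro-style mix on top of std::mt19937_64 would still be
// portable, but normal_distribution is not; we use explicit Box-Muller.
struct Rng {
  uint64_t s;
  explicit Rng(uint64_t seed) : s(seed ? seed : 0x9e3779b97f4a7c15ULL) {}
  uint64_t next() {
    // splitmix64
    uint64_t z = (s += 0x9e3779b97f4a7c15ULL);
    z = (z ^ (z >> 30)) * 0xbf58476d1ce4e5b9ULL;
    z = (z ^ (z >> 27)) * 0x94d049bb133111ebULL;
    return z ^ (z >> 31);
  }
  double unif() { return (next() >> 11) * (1.0 / 9007199254740992.0); }
  double normal() {
    double u1 = 0.0;
    while (u1 <= 1e-300) u1 = unif();
    double u2 = unif();
    return std::sqrt(-2.0 * std::log(u1)) * std::cos(6.283185307179586 * u2);
  }
  int unifInt(int n) { return (int)(unif() * n) % n; }
};

struct Network {
  int nNeurons;                 // cortical neurons
  int nThal;
  std::vector<int> popOf;       // per cortical neuron, 0..7
  std::vector<uint8_t> popInh;  // per population, cortical
  // out-adjacency (CSR) over pre id; cortical pre in [0, nNeurons),
  // thalamic pre in [nNeurons, nNeurons + nThal)
  std::vector<int64_t> rowPtr;
  std::vector<int> post;
  std::vector<float> w;         // pA, already signed
  std::vector<uint8_t> delay;   // integration steps, >= 1
  int maxDelay;
};

// pairs: src, tgt population indices (0-based, src may be 8 = thalamus),
// k synapses per pair, weight mean (pA, doubled where applicable), weight
// sign (+1/-1 by source type), delay mean/sd (steps).
// [[Rcpp::export]]
SEXP cpp_build_network(IntegerVector popSizes, LogicalVector popIsInh,
                       IntegerVector pairSrc, IntegerVector pairTgt,
                       NumericVector pairK, NumericVector wMu,
                       NumericVector wSd, NumericVector wSign,
                       NumericVector dMuSteps, NumericVector dSdSteps,
                       int seed) {
  int nPop = popSizes.size();       // 9 incl thalamus (last)
  std::vector<int> popStart(nPop + 1, 0);
  for (int p = 0; p < nPop; ++p) popStart[p + 1] = popStart[p] + popSizes[p];
  Network* net = new Network();
  net->nThal = popSizes[nPop - 1];
  net->nNeurons = popStart[nPop - 1];
  net->popOf.resize(net->nNeurons);
  for (int p = 0; p < nPop - 1; ++p)
    for (int i = popStart[p]; i < popStart[p + 1]; ++i) net->popOf[i] = p;
  net->popInh.assign(popIsInh.begin(), popIsInh.end());

  int64_t kTot = 0;
  for (int e = 0; e < pairK.size(); ++e) kTot += (int64_t) std::llround(pairK[e]);
  int nPre = net->nNeurons + net->nThal;

  Rng rng((uint64_t) seed * 0x5851f42d4c957f2dULL + 12345ULL);

  // first pass: out-degree histogram so edges can be placed pre-sorted
  std::vector<int64_t> deg(nPre, 0);
  std::vector<std::vector<int>> preDraw(pairK.size());
  for (int e = 0; e < pairK.size(); ++e) {
    int64_t k = (int64_t) std::llround(pairK[e]);
    int sp = pairSrc[e];
    int base = popStart[sp], sz = popSizes[sp];
    preDraw[e].resize(k);
    for (int64_t j = 0; j < k; ++j) {
      int pre = base + rng.unifInt(sz);
      preDraw[e][j] = pre;
      ++deg[pre];
    }
  }
  net->rowPtr.resize(nPre + 1);
  net->rowPtr[0] = 0;
  for (int i = 0; i < nPre; ++i) net->rowPtr[i + 1] = net->rowPtr[i] + deg[i];
  net->post.resize(kTot);
  net->w.resize(kTot);
  net->delay.resize(kTot);
  std::vector<int64_t> cursor(net->rowPtr.begin(), net->rowPtr.end() - 1);
  int maxD = 1;
  for (int e = 0; e < pairK.size(); ++e) {
    int tp = pairTgt[e];
    int tbase = popStart[tp], tsz = popSizes[tp];
    double mu = wMu[e], sd = wSd[e], sg = wSign[e];
    double dm = dMuSteps[e], ds = dSdSteps[e];
    for (size_t j = 0; j < preDraw[e].size(); ++j) {
      int pre = preDraw[e][j];
      int64_t at = cursor[pre]++;
      net->post[at] = tbase + rng.unifInt(tsz);
      double wv = mu + sd * rng.normal();
      while (wv <= 0.0) wv = mu + sd * rng.normal(); // redraw, negatives vanishingly rare
      net->w[at] = (float)(sg * wv);
      int dsteps = (int) std::lround(dm + ds * rng.normal());
      if (dsteps < 1) dsteps = 1;
      if (dsteps > 200) dsteps = 200;
      net->delay[at] = (uint8_t) dsteps;
      if (dsteps > maxD) maxD = dsteps;
    }
  }
  net->maxDelay = maxD;
  XPtr<Network> ptr(net, true);
  return ptr;
}

// [[Rcpp::export]]
List cpp_network_summary(SEXP netPtr) {
  XPtr<Network> net(netPtr);
  int nPre = net->nNeurons + net->nThal;
  double wsum = 0, wsum2 = 0;
  int64_t nEx = 0;
  for (size_t i = 0; i < net->w.size(); ++i) {
    if (net->w[i] > 0) { wsum += net->w[i]; wsum2 += (double) net->w[i] * net->w[i]; ++nEx; }
  }
  double wMean = nEx ? wsum / nEx : NA_REAL;
  double wSd = nEx > 1 ? std::sqrt(wsum2 / nEx - wMean * wMean) : NA_REAL;
  return List::create(
    _["nNeurons"] = net->nNeurons, _["nThal"] = net->nThal,
    _["nSynapses"] = (double) net->post.size(),
    _["nPre"] = nPre, _["excWeightMean"] = wMean, _["excWeightSd"] = wSd,
    _["maxDelaySteps"] = net->maxDelay);
}

// Synapse count between two populations (for construction checks).
// [[Rcpp::export]]
double cpp_pair_synapse_count(SEXP netPtr, int srcPop0, int tgtPop0,
                              IntegerVector popSizes) {
  XPtr<Network> net(netPtr);
  int nPop = popSizes.size();
  std::vector<int> popStart(nPop + 1, 0);
  for (int p = 0; p < nPop; ++p) popStart[p + 1] = popStart[p] + popSizes[p];
  int64_t cnt = 0;
  for (int pre = popStart[srcPop0]; pre < popStart[srcPop0 + 1]; ++pre) {
    for (int64_t e = net->rowPtr[pre]; e < net->rowPtr[pre + 1]; ++e) {
      int tp = net->post[e] >= popStart[tgtPop0] && net->post[e] < popStart[tgtPop0 + 1];
      if (tp) ++cnt;
    }
  }
  return (double) cnt;
}

// Simulate interleaved touch trials.
// Per-population parameter vectors are over the 8 cortical populations.
// Returns per-neuron spike counts in the baseline window [baseFrom, touchOn)
// and touch window [touchOn, touchOff) of every trial.
// [[Rcpp::export]]
List cpp_simulate_circuit(SEXP netPtr, NumericVector bgCurrent,
                          double dt, double tauM, double Cm, double Vr,
                          double Vth, double tauRef, double tauSyn,
                          double initMu, double initSd,
                          int nTrials, double trialLen, double touchOn,
                          double touchOff, double baseFrom,
                          double thalRate, double vrShiftInh, double rmFactorExc,
                          double rateCeiling, int seed) {
  XPtr<Network> netp(netPtr);
  Network* net = netp.get();
  int N = net->nNeurons, nThal = net->nThal;
  const int* popOfA = net->popOf.data();
  const int64_t* rowPtrA = net->rowPtr.data();
  const int* postA = net->post.data();
  const float* wA = net->w.data();
  const uint8_t* delayA = net->delay.data();
  int stepsPerTrial = (int) std::lround(trialLen / dt);
  int touchOnStep = (int) std::lround(touchOn / dt);
  int touchOffStep = (int) std::lround(touchOff / dt);
  int baseFromStep = (int) std::lround(baseFrom / dt);
  int refSteps = (int) std::lround(tauRef / dt);
  int nPop = 8;

  Rng rng((uint64_t) seed * 0x2545f4914f6cdd1dULL + 99ULL);

  std::vector<double> V(N), Isyn(N, 0.0);
  std::vector<int> refrac(N, 0);
  for (int i = 0; i < N; ++i) V[i] = initMu + initSd * rng.normal();

  int nDelay = net->maxDelay + 1;
  std::vector<float> ring((size_t) nDelay * N, 0.0f);

  IntegerMatrix countsBase(N, nTrials), countsTouch(N, nTrials);
  int* cbA = countsBase.begin();
  int* ctA = countsTouch.begin();

  // exact integration constants; two parameter sets per population:
  // normal, and touch-modulated (only used in modulated trials during touch)
  double B = std::exp(-dt / tauSyn);
  auto makeConst = [&](double tm, double vLeak, double iext, double& A,
                       double& k, double& vInf) {
    A = std::exp(-dt / tm);
    k = tm * tauSyn / (Cm * (tauSyn - tm)); // particular-solution gain
    vInf = vLeak + iext * tm / Cm;
  };
  std::vector<double> A0(nPop), k0(nPop), vInf0(nPop);
  std::vector<double> A1(nPop), k1(nPop), vInf1(nPop);
  std::vector<double> vReset0(nPop, Vr), vReset1(nPop, Vr);
  for (int p = 0; p < nPop; ++p) {
    double iext = bgCurrent[p];
    makeConst(tauM, Vr, iext, A0[p], k0[p], vInf0[p]);
    bool inh = net->popInh[p];
    double tmMod = (!inh && rmFactorExc != 1.0) ? tauM * rmFactorExc : tauM;
    double vLeakMod = inh ? Vr + vrShiftInh : Vr;
    makeConst(tmMod, vLeakMod, iext, A1[p], k1[p], vInf1[p]);
    vReset1[p] = vLeakMod;
  }

  // time arguments are in ms, voltages in mV, currents in pA, Cm in pF
  double pThal = thalRate * dt;
  int64_t ceilingCount = (int64_t)(rateCeiling * N * 0.1); // spikes per 100 ms
  int stepsPer100ms = (int) std::lround(100.0 / dt);
  int64_t windowSpikes = 0;
  int sinceCheck = 0;

  std::vector<int> spikers;
  spikers.reserve(N / 10 + 16);

  for (int trial = 0; trial < nTrials; ++trial) {
    bool modulated = (trial % 2) == 1;
    for (int st = 0; st < stepsPerTrial; ++st) {
      bool touch = st >= touchOnStep && st < touchOffStep;
      bool useMod = modulated && touch;
      const double* A = useMod ? A1.data() : A0.data();
      const double* kk = useMod ? k1.data() : k0.data();
      const double* vInf = useMod ? vInf1.data() : vInf0.data();
      const double* vRst = useMod ? vReset1.data() : vReset0.data();
      int slot = (int)(((int64_t) trial * stepsPerTrial + st) % nDelay);
      float* arrive = &ring[(size_t) slot * N];
      spikers.clear();
      for (int i = 0; i < N; ++i) {
        double Is = Isyn[i] + arrive[i];
        arrive[i] = 0.0f;
        int p = popOfA[i];
        double v = V[i];
        if (refrac[i] > 0) {
          --refrac[i];
          v = vRst[p]; // clamped at reset during refractory period
        } else {
          v = vInf[p] + (v - vInf[p] - kk[p] * Is) * A[p] + kk[p] * Is * B;
          if (v >= Vth) {
            spikers.push_back(i);
            v = vRst[p];
            refrac[i] = refSteps;
          }
        }
        V[i] = v;
        Isyn[i] = Is * B;
      }
      // thalamic drive: Poisson (Bernoulli per step) during touch
      if (touch && pThal > 0.0) {
        for (int tnum = 0; tnum < nThal; ++tnum) {
          if (rng.unif() < pThal) spikers.push_back(N + tnum);
        }
      }
      // deliver spikes
      bool inBase = st >= baseFromStep && st < touchOnStep;
      for (size_t sidx = 0; sidx < spikers.size(); ++sidx) {
        int i = spikers[sidx];
        if (i < N) {
          if (inBase) ++cbA[(size_t) trial * N + i];
          else if (touch) ++ctA[(size_t) trial * N + i];
          ++windowSpikes;
        }
        int64_t e0 = rowPtrA[i], e1 = rowPtrA[i + 1];
        for (int64_t e = e0; e < e1; ++e) {
          int dslot = slot + delayA[e];
          if (dslot >= nDelay) dslot -= nDelay;
          ring[(size_t) dslot * N + postA[e]] += wA[e];
        }
      }
      if (++sinceCheck == stepsPer100ms) {
        if (windowSpikes > ceilingCount) {
          stop("runaway network activity: population rate above ceiling (%.0f Hz average)",
               (double) windowSpikes / (N * 0.1));
        }
        windowSpikes = 0;
        sinceCheck = 0;
      }
    }
    Rcpp::checkUserInterrupt();
  }

  IntegerVector popOf(N);
  for (int i = 0; i < N; ++i) popOf[i] = net->popOf[i] + 1;
  return List::create(
    _["countsBase"] = countsBase, _["countsTouch"] = countsTouch,
    _["popOf"] = popOf);
}

// Single-neuron exact integrator (no spiking) for validation against the
// closed-form membrane solution under constant current.
// [[Rcpp::export]]
NumericVector cpp_lif_single(double V0, double Iext, int nSteps, double dt,
                             double tauM, double Cm, double Vr) {
  NumericVector out(nSteps + 1);
  double A = std::exp(-dt / tauM);
  double vInf = Vr + Iext * tauM / Cm;
  double v = V0;
  out[0] = v;
  for (int i = 1; i <= nSteps; ++i) {
    v = vInf + (v - vInf) * A;
    out[i] = v;
  }
  return out;
}
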