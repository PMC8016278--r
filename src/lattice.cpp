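#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

// Stochastic square-lattice model of cooperative AMPAR binding at the PSD.
// Slots are updated synchronously per time step with the neighbour fraction
// chi frozen at the start of the step; the mobile pool U is advanced by
// tau-leap Poisson draws of the trafficking fluxes. Receptors carry a
// bleached/unbleached label so the same core drives FRAP simulations.

// [[Rcpp::export(name = ".lattice_sim")]]
List lattice_sim(int N, double tEnd, double dt, double burnIn,
                 bool startFull,
                 double alpha, double kUB, double kBU,
                 double kIn, double kExo, double SExo,
                 double kEndo, double kOut, double ASpine,
                 double U0, bool clampU, double conc,
                 double bleachTime, int thin) {
  const int P = N * N;
  const int nsteps = (int)std::lround(tEnd / dt);
  const int nburn = (int)std::lround(burnIn / dt);
  const int bleachStep = bleachTime >= 0.0
    ? (int)std::lround(bleachTime / dt) : -1;

  std::vector<int> occ(P, startFull ? 1 : 0);   // slot occupancy
  std::vector<int> bl(P, 0);                    // 1 = bleached receptor
  std::vector<int> nb(P);                       // occupied neighbours
  std::vector<int> cand; cand.reserve(P);
  std::vector<double> boundTime(P, 0.0);
  std::vector<int> bindCount(P, 0), unbindCount(P, 0);

  long Uu = (long)std::lround(U0), Ub = 0;      // mobile unbleached/bleached

  // conditional-rate accumulators indexed by B (Eqs for <k^UB>, <k^BU>)
  NumericVector cnt(P + 1), sUB(P + 1), sBU(P + 1);
  double Bsum = 0.0, B2sum = 0.0; long nsamp = 0;
  long bindsTot = 0, unbindsTot = 0;

  const int nrec = nsteps / thin + 1;
  NumericMatrix rec(nrec, 5); // t, Uu, Ub, Bu, Bb
  int irec = 0;

  auto neighbours = [&](void) {
    for (int r = 0; r < N; r++) {
      for (int c = 0; c < N; c++) {
        int s = 0;
        for (int dr = -1; dr <= 1; dr++)
          for (int dc = -1; dc <= 1; dc++) {
            if (dr == 0 && dc == 0) continue;
            int rr = r + dr, cc = c + dc;
            if (rr >= 0 && rr < N && cc >= 0 && cc < N)
              s += occ[rr * N + cc];
          }
        nb[r * N + c] = s;
      }
    }
  };

  auto record = [&](int step) {
    long Bu = 0, Bb = 0;
    for (int i = 0; i < P; i++) if (occ[i]) { if (bl[i]) Bb++; else Bu++; }
    rec(irec, 0) = step * dt; rec(irec, 1) = (double)Uu;
    rec(irec, 2) = (double)Ub; rec(irec, 3) = (double)Bu;
    rec(irec, 4) = (double)Bb;
    irec++;
  };
  record(0);

  for (int step = 0; step < nsteps; step++) {
    if (step == bleachStep) { // photobleach everything currently in the spine
      for (int i = 0; i < P; i++) if (occ[i]) bl[i] = 1;
      Ub += Uu; Uu = 0;
    }
    neighbours();
    int B = 0;
    for (int i = 0; i < P; i++) B += occ[i];

    // conditional means over empty / occupied slots at this B
    // (alpha == 0 is the non-cooperative control: both rates constant)
    const bool coopOn = alpha > 0.0;
    double mUB = 0.0, mBU = 0.0; int ne = 0, no = 0;
    for (int i = 0; i < P; i++) {
      double chi = coopOn ? nb[i] / 8.0 : 0.0;
      if (occ[i]) { mBU += kBU * (1.0 - chi); no++; }
      else        { mUB += kUB * (alpha * chi + 1.0); ne++; }
    }
    cnt[B] += 1.0;
    if (ne > 0) sUB[B] += mUB / ne;
    if (no > 0) sBU[B] += mBU / no;
    if (step >= nburn) { Bsum += B; B2sum += (double)B * B; nsamp++; }

    double U = (double)(Uu + Ub);
    double cc = clampU ? conc : U / ASpine;

    // synchronous Bernoulli sweep
    cand.clear();
    std::vector<int> unbinds; unbinds.reserve(16);
    for (int i = 0; i < P; i++) {
      double chi = coopOn ? nb[i] / 8.0 : 0.0;
      if (occ[i]) {
        double pu = kBU * (1.0 - chi) * dt;
        if (pu > 1.0) stop("unbinding probability %g > 1; reduce dt", pu);
        if (unif_rand() < pu) unbinds.push_back(i);
      } else {
        double pb = kUB * (alpha * chi + 1.0) * cc * dt;
        if (pb > 1.0) stop("binding probability %g > 1; reduce dt", pb);
        if (unif_rand() < pb) cand.push_back(i);
      }
    }
    // binding is limited by the available mobile receptors
    long avail = clampU ? (long)P : (Uu + Ub);
    if ((long)cand.size() > avail) {
      for (long i = (long)cand.size() - 1; i > 0; i--) { // partial shuffle
        long j = (long)std::floor(unif_rand() * (i + 1));
        std::swap(cand[i], cand[j]);
      }
      cand.resize(avail);
    }
    for (int i : unbinds) {
      occ[i] = 0; unbindCount[i]++; unbindsTot++;
      if (!clampU) { if (bl[i]) Ub++; else Uu++; }
      bl[i] = 0;
    }
    for (int i : cand) {
      occ[i] = 1; bindCount[i]++; bindsTot++;
      if (clampU) { bl[i] = 0; }
      else {
        // draw the bound receptor's label from the mobile pool
        double pBleach = (Uu + Ub) > 0 ? (double)Ub / (double)(Uu + Ub) : 0.0;
        if (unif_rand() < pBleach) { bl[i] = 1; Ub--; }
        else { bl[i] = 0; Uu--; }
      }
    }
    if (!clampU) {
      // trafficking fluxes of the mobile pool (tau-leap); influx is unbleached
      long inflow = (long)SExo * (long)R::rpois(kExo * dt)
        + (long)R::rpois(kIn * dt);
      double Unow = (double)(Uu + Ub);
      long outflow = (long)R::rpois((kEndo + kOut) * Unow / ASpine * dt);
      if (outflow > Uu + Ub) outflow = Uu + Ub;
      for (long k = 0; k < outflow; k++) {
        double pB = (Uu + Ub) > 0 ? (double)Ub / (double)(Uu + Ub) : 0.0;
        if (unif_rand() < pB) Ub--; else Uu--;
      }
      Uu += inflow;
    }
    for (int i = 0; i < P; i++) if (occ[i]) boundTime[i] += dt;
    if ((step + 1) % thin == 0) record(step + 1);
  }

  colnames(rec) = CharacterVector::create("t", "Uu", "Ub", "Bu", "Bb");
  double Bbar = nsamp > 0 ? Bsum / nsamp : NA_REAL;
  double Bvar = nsamp > 0 ? B2sum / nsamp - Bbar * Bbar : NA_REAL;
  return List::create(
    _["series"] = rec,
    _["cnt"] = cnt, _["sUB"] = sUB, _["sBU"] = sBU,
    _["Bbar"] = Bbar, _["Bvar"] = Bvar, _["nSampled"] = (double)nsamp,
    _["boundTime"] = NumericVector(boundTime.begin(), boundTime.end()),
    _["bindCount"] = IntegerVector(bindCount.begin(), bindCount.end()),
    _["unbindCount"] = IntegerVector(unbindCount.begin(), unbindCount.end()),
    _["bindsTotal"] = (double)bindsTot, _["unbindsTotal"] = (double)unbindsTot);
}
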