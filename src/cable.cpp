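// Implicit compartmental cable solver on a branched tree.
//
// The membrane equation per compartment i is
//   cm_i dV_i/dt = gl_i (EL - V_i) + sum_c gbar_ci x^p (E_c - V_i)
//                  + sum_axial g_ij (V_j - V_i) + I_inj,
// integrated with a theta-method (theta = 1: backward Euler, 0.5:
// Crank-Nicolson) for the voltage, operator-split from the gating
// variables, which relax exactly toward x_inf(V) within each step.
// The linear tree system is solved by ordered elimination (leaf-to-root,
// then back-substitution), unconditionally stable for the passive part.
// Compartments are ordered so that parent[i] < i; the root (index 0) is
// the soma and is the only compartment that can be voltage-clamped.
//
// Units: mV, ms, nF, uS, nA.

#include <Rcpp.h>
#include <cmath>
#include <vector>
using namespace Rcpp;

struct GateSpec {
  double V_half, k, tau_star;
  int expo;
  bool inact, fixed_tau;
};

struct ChannelSpec {
  double E;
  std::vector<double> gbar;               // uS per compartment
  std::vector<GateSpec> gates;
  std::vector<std::vector<double> > x;    // gate values [gate][comp]
};

static inline void gate_update(const GateSpec& g, double V, double dt,
                               double& x) {
  double s = g.inact ? -1.0 : 1.0;
  double u = s * (V - g.V_half) / g.k;
  double xinf = 1.0 / (1.0 + std::exp(-u));
  double tau;
  if (g.fixed_tau) {
    tau = g.tau_star;
  } else {
    double au = std::fabs(u);
    tau = (au < 1e-6) ? g.tau_star
                      : 2.0 * g.tau_star * std::tanh(u / 2.0) / u;
  }
  x = xinf + (x - xinf) * std::exp(-dt / tau);
}

// [[Rcpp::export(name = ".sim_run_cpp")]]
List sim_run_cpp(List model, List state, double dt, int n_steps,
                 List stim, bool clamp, double clamp_value,
                 IntegerVector record, int record_every,
                 bool record_gates, bool record_currents,
                 double theta, double t0) {
  IntegerVector parent = model["parent"];
  NumericVector cm = model["cm"];
  NumericVector g_ax = model["g_ax"];
  NumericVector gl = model["gl"];
  double EL = as<double>(model["EL"]);
  List channels = model["channels"];
  int n = parent.size();
  int nch = channels.size();

  std::vector<ChannelSpec> ch(nch);
  List state_gates = state["gates"];
  for (int c = 0; c < nch; ++c) {
    List cc = channels[c];
    ch[c].E = as<double>(cc["E"]);
    NumericVector gb = cc["gbar"];
    ch[c].gbar.assign(gb.begin(), gb.end());
    List gts = cc["gates"];
    int ng = gts.size();
    ch[c].gates.resize(ng);
    ch[c].x.resize(ng);
    NumericMatrix xs = state_gates[c];   // n x ng
    for (int g = 0; g < ng; ++g) {
      List gg = gts[g];
      ch[c].gates[g].V_half = as<double>(gg["V_half"]);
      ch[c].gates[g].k = as<double>(gg["k_slope"]);
      ch[c].gates[g].tau_star = as<double>(gg["tau_star"]);
      ch[c].gates[g].expo = as<int>(gg["exponent"]);
      ch[c].gates[g].inact = as<bool>(gg["is_inactivation"]);
      ch[c].gates[g].fixed_tau = as<bool>(gg["fixed_tau"]);
      ch[c].x[g].resize(n);
      for (int i = 0; i < n; ++i) ch[c].x[g][i] = xs(i, g);
    }
  }

  NumericVector V0 = state["V"];
  std::vector<double> V(V0.begin(), V0.end());

  // stimuli
  int nstim = stim.size();
  std::vector<int> s_comp(nstim);
  std::vector<double> s_amp(nstim), s_on(nstim), s_off(nstim);
  for (int s = 0; s < nstim; ++s) {
    List ss = stim[s];
    s_comp[s] = as<int>(ss["comp"]);
    s_amp[s] = as<double>(ss["amp"]);
    s_on[s] = as<double>(ss["t_on"]);
    s_off[s] = as<double>(ss["t_off"]);
  }

  int nrec_t = n_steps / record_every + 1;
  int nprobe = record.size();
  NumericMatrix Vrec(nrec_t, nprobe);
  NumericVector trec(nrec_t);
  NumericVector Iclamp(clamp ? nrec_t : 0);
  List gate_rec, curr_rec;
  std::vector<NumericMatrix> grec, crec;
  if (record_gates) {
    for (int c = 0; c < nch; ++c)
      for (size_t g = 0; g < ch[c].gates.size(); ++g)
        grec.push_back(NumericMatrix(nrec_t, nprobe));
  }
  if (record_currents) {
    for (int c = 0; c < nch; ++c) crec.push_back(NumericMatrix(nrec_t, nprobe));
  }

  std::vector<double> D(n), rhs(n), gcond(n), Iinj(n), axial_old(n);
  std::vector<std::vector<double> > gch(nch, std::vector<double>(n));

  int irec = 0;
  for (int step = 0; step <= n_steps; ++step) {
    double tnow = t0 + step * dt;

    if (step > 0) {
      // 1. gate update (exact exponential relaxation at current V)
      for (int c = 0; c < nch; ++c) {
        for (size_t g = 0; g < ch[c].gates.size(); ++g) {
          const GateSpec& gs = ch[c].gates[g];
          std::vector<double>& x = ch[c].x[g];
          const std::vector<double>& gb = ch[c].gbar;
          for (int i = 0; i < n; ++i)
            if (gb[i] > 0) gate_update(gs, V[i], dt, x[i]);
        }
      }
      // 2. channel conductances
      for (int c = 0; c < nch; ++c) {
        std::vector<double>& gc = gch[c];
        for (int i = 0; i < n; ++i) {
          double gb = ch[c].gbar[i];
          if (gb > 0) {
            double prod = 1.0;
            for (size_t g = 0; g < ch[c].gates.size(); ++g) {
              double xv = ch[c].x[g][i];
              for (int e = 0; e < ch[c].gates[g].expo; ++e) prod *= xv;
            }
            gc[i] = gb * prod;
          } else gc[i] = 0.0;
        }
      }
      // 3. injections active during this step
      std::fill(Iinj.begin(), Iinj.end(), 0.0);
      double tmid = tnow - dt; // stimulus evaluated at start of step
      for (int s = 0; s < nstim; ++s)
        if (tmid >= s_on[s] && tmid < s_off[s]) Iinj[s_comp[s]] += s_amp[s];

      // 4. assemble theta-method system
      double om = 1.0 - theta;
      if (om > 0) {
        std::fill(axial_old.begin(), axial_old.end(), 0.0);
        for (int i = 1; i < n; ++i) {
          int p = parent[i];
          double ia = g_ax[i] * (V[p] - V[i]);
          axial_old[i] += ia;
          axial_old[p] -= ia;
        }
      }
      for (int i = 0; i < n; ++i) {
        double gtot = gl[i];
        double gE = gl[i] * EL;
        for (int c = 0; c < nch; ++c) {
          gtot += gch[c][i];
          gE += gch[c][i] * ch[c].E;
        }
        D[i] = cm[i] / dt + theta * gtot;
        rhs[i] = cm[i] / dt * V[i] + theta * gE + Iinj[i];
        if (om > 0) rhs[i] += om * (gE - gtot * V[i] + axial_old[i]);
      }
      for (int i = 1; i < n; ++i) {
        int p = parent[i];
        double ga = theta * g_ax[i];
        D[i] += ga;
        D[p] += ga;
      }
      // 5. Hines elimination (parent[i] < i)
      for (int i = n - 1; i >= 1; --i) {
        int p = parent[i];
        double ga = theta * g_ax[i];
        double f = ga / D[i];
        D[p] -= f * ga;
        rhs[p] += f * rhs[i];
      }
      double Vroot_old = V[0];
      V[0] = clamp ? clamp_value : rhs[0] / D[0];
      for (int i = 1; i < n; ++i)
        V[i] = (rhs[i] + theta * g_ax[i] * V[parent[i]]) / D[i];
      if (!std::isfinite(V[0]) || !std::isfinite(V[n - 1])) {
        stop("integration diverged at t = %f ms", tnow);
      }
      if (clamp && step % record_every == 0) {
        // electrode current balancing membrane + axial + capacitive load
        double Imem = gl[0] * (EL - V[0]) + Iinj[0];
        for (int c = 0; c < nch; ++c) Imem += gch[c][0] * (ch[c].E - V[0]);
        double Iax = 0.0;
        for (int i = 1; i < n; ++i)
          if (parent[i] == 0) Iax += g_ax[i] * (V[i] - V[0]);
        double Icap = cm[0] * (V[0] - Vroot_old) / dt;
        Iclamp[irec] = Icap - Imem - Iax;
      }
    } else if (clamp) {
      V[0] = clamp_value;
      Iclamp[0] = 0.0;
    }

    if (step % record_every == 0) {
      trec[irec] = tnow;
      for (int j = 0; j < nprobe; ++j) Vrec(irec, j) = V[record[j]];
      if (record_gates) {
        int idx = 0;
        for (int c = 0; c < nch; ++c)
          for (size_t g = 0; g < ch[c].gates.size(); ++g) {
            for (int j = 0; j < nprobe; ++j)
              grec[idx](irec, j) = ch[c].x[g][record[j]];
            ++idx;
          }
      }
      if (record_currents && step > 0) {
        for (int c = 0; c < nch; ++c)
          for (int j = 0; j < nprobe; ++j)
            crec[c](irec, j) = gch[c][record[j]] * (ch[c].E - V[record[j]]);
      }
      ++irec;
    }
  }

  // final state
  NumericVector Vfin(V.begin(), V.end());
  List gfin(nch);
  for (int c = 0; c < nch; ++c) {
    int ng = ch[c].gates.size();
    NumericMatrix xs(n, ng);
    for (int g = 0; g < ng; ++g)
      for (int i = 0; i < n; ++i) xs(i, g) = ch[c].x[g][i];
    gfin[c] = xs;
  }

  List out = List::create(
    _["t"] = trec, _["V"] = Vrec,
    _["state"] = List::create(_["V"] = Vfin, _["gates"] = gfin),
    _["I_clamp"] = Iclamp);
  if (record_gates) {
    List gl_out(grec.size());
    for (size_t i = 0; i < grec.size(); ++i) gl_out[i] = grec[i];
    out["gates"] = gl_out;
  }
  if (record_currents) {
    List cl_out(crec.size());
    for (size_t i = 0; i < crec.size(); ++i) cl_out[i] = crec[i];
    out["currents"] = cl_out;
  }
  return out;
}
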