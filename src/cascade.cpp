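#include <Rcpp.h>
using namespace Rcpp;

// Per-step event probability for a hazard given in s^-1 and a step in ms.
static inline double pstep(double rate_s, double dt_ms) {
  if (rate_s <= 0.0) return 0.0;
  return 1.0 - std::exp(-rate_s * dt_ms / 1000.0);
}

static inline int rbin(int n, double p) {
  if (n <= 0 || p <= 0.0) return 0;
  if (p >= 1.0) return n;
  return (int) R::rbinom((double) n, p);
}

// Fixed-step binomial leap simulation of one photon-activation event in a
// single microvillus. Per-molecule binomial draws are exact for constant
// hazards within a step, so low copy numbers need no special casing.
//
// State: M* (one activated rhodopsin), free active Galpha, Galpha-PLC
// complexes, DAG, open TRP channels, plus a deterministic dimensionless
// calcium variable feeding back on channel gating and turnover.
// Rates are s^-1, times ms. Uses R's RNG: seed with set.seed() upstream.
// [[Rcpp::export]]
List simulate_bump_cpp(List par) {
  const double dt       = as<double>(par["dt"]);
  const int n_steps     = as<int>(par["n_steps"]);

  const double k_exch   = as<double>(par["k_exch"]);      // GDP->GTP, per M*-G encounter
  const int g_total     = as<int>(par["g_total"]);
  const double g_pool0  = as<double>(par["g_pool0"]);     // control G pool (rate normalizer)
  const int plc_total   = as<int>(par["plc_total"]);
  const double plc_pool0= as<double>(par["plc_pool0"]);
  const double k_bind   = as<double>(par["k_bind"]);      // Galpha-PLC encounter at control PLC
  const double k_ga_loss= as<double>(par["k_ga_loss"]);
  const double k_m      = as<double>(par["k_m"]);         // M* deactivation
  const double k_gap    = as<double>(par["k_gap"]);       // complex turnoff (GAP)
  const double k_hyd    = as<double>(par["k_hyd"]);       // PIP2 breakdown per complex
  const int pip2_total  = as<int>(par["pip2_total"]);
  const double k_ddeg   = as<double>(par["k_ddeg"]);      // DAG kinase
  const double k_open   = as<double>(par["k_open"]);
  const double k_close  = as<double>(par["k_close"]);
  const double dag_k    = as<double>(par["dag_k"]);       // DAG half-activation count
  const double hill     = as<double>(par["hill"]);
  const double sens     = as<double>(par["sens"]);        // channel sensitivity to DAG
  const int n_channels  = as<int>(par["n_channels"]);
  const double ca_in    = as<double>(par["ca_in"]);       // Ca influx per open channel per ms
  const double tau_ca   = as<double>(par["tau_ca"]);      // Ca clearance, ms
  const double ca_open  = as<double>(par["ca_open"]);     // positive feedback on opening
  const double ca_close = as<double>(par["ca_close"]);    // negative feedback on closing
  const double ca_gap   = as<double>(par["ca_gap"]);      // Ca acceleration of GAP
  const double ca_m     = as<double>(par["ca_m"]);        // Ca acceleration of M* shutoff
  const double ca_ddeg  = as<double>(par["ca_ddeg"]);     // Ca acceleration of DAG removal
  const double ca_half  = as<double>(par["ca_half"]);     // half-saturation of Ca feedback
  const double pkc      = as<double>(par["pkc"]);         // PKC activity multiplier
  const double pkc_w    = as<double>(par["pkc_w"]);       // PKC share of turnover at control

  IntegerVector n_ga(n_steps), n_gaplc(n_steps), n_dag(n_steps), n_open_v(n_steps);

  int m_active = 1;
  int g_free = g_total, ga = 0, gaplc = 0, plc_free = plc_total;
  int pip2 = pip2_total, dag = 0, n_open = 0;
  double ca = 0.0;
  // PKC scales the Ca-dependent termination terms only, leaving the
  // activation phase untouched: at pkc = 1 the factor is 1.
  const double fpkc = 1.0 + pkc_w * (pkc - 1.0);

  for (int i = 1; i < n_steps; ++i) {
    if (m_active == 0 && ga == 0 && gaplc == 0 && dag == 0 && n_open == 0) {
      // cascade extinct: remaining samples stay zero
      break;
    }
    // saturating Ca feedback signal in [0, 1)
    const double sca = ca / (ca_half + ca);
    // G-protein activation by M* (rate normalized to the control pool)
    if (m_active && g_free > 0) {
      int act = rbin(g_free, pstep(k_exch / g_pool0, dt));
      g_free -= act; ga += act;
    }
    // M* deactivation (arrestin-like, PKC-accelerated)
    if (m_active && unif_rand() < pstep(k_m * (1.0 + ca_m * sca * fpkc), dt))
      m_active = 0;
    // Galpha finds PLC (diffusion-limited encounter)
    if (ga > 0 && plc_free > 0) {
      int bnd = rbin(ga, pstep(k_bind * plc_free / plc_pool0, dt));
      if (bnd > plc_free) bnd = plc_free;
      ga -= bnd; plc_free -= bnd; gaplc += bnd;
    }
    // spontaneous Galpha loss
    if (ga > 0) ga -= rbin(ga, pstep(k_ga_loss, dt));
    // complex turnoff (GAP activity, Ca- and PKC-accelerated)
    if (gaplc > 0) {
      int off = rbin(gaplc, pstep(k_gap * (1.0 + ca_gap * sca * fpkc), dt));
      gaplc -= off; plc_free += off;
    }
    // PIP2 hydrolysis -> DAG
    if (gaplc > 0 && pip2 > 0) {
      int made = rbin(pip2, pstep(k_hyd * gaplc / (double) pip2_total, dt));
      pip2 -= made; dag += made;
    }
    // DAG removal (DAG kinase, Ca- and PKC-accelerated)
    if (dag > 0) dag -= rbin(dag, pstep(k_ddeg * (1.0 + ca_ddeg * sca * fpkc), dt));
    // TRP gating: DAG-driven opening with Hill cooperativity and positive
    // Ca feedback; closing with negative Ca feedback
    double x = sens * (double) dag / dag_k;
    double act_drive = std::pow(x, hill);
    double p_open = pstep(k_open * act_drive / (1.0 + act_drive)
                          * (1.0 + ca_open * sca), dt);
    double p_close = pstep(k_close * (1.0 + ca_close * sca * fpkc), dt);
    int opening = rbin(n_channels - n_open, p_open);
    int closing = rbin(n_open, p_close);
    n_open += opening - closing;
    // calcium: deterministic influx/clearance in arbitrary units
    ca += dt * (ca_in * n_open) - dt * ca / tau_ca;
    if (ca < 0.0) ca = 0.0;

    n_ga[i] = ga; n_gaplc[i] = gaplc; n_dag[i] = dag; n_open_v[i] = n_open;
  }

  return List::create(_["n_Ga"] = n_ga, _["n_GaPLC"] = n_gaplc,
                      _["n_DAG"] = n_dag, _["n_open"] = n_open_v);
}
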