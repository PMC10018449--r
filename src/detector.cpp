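#include <Rcpp.h>
#include <algorithm>
#include <cmath>
using namespace Rcpp;

// Streaming droplet-event detector: a per-sample state machine with
// constant memory, designed so that feeding the trace in chunks of any size
// yields bitwise-identical output to a single whole-trace pass.
//
// Per sample: a short causal moving average (ring buffer) suppresses
// single-sample noise; a baseline estimate is maintained by an exponential
// moving average updated only from in-band samples (so dips and shoulders
// never drag it); an event opens when the smoothed signal leaves the
// baseline band (below baseline - enter_delta, or above baseline +
// shoulder_delta for an edge shoulder) and closes after `debounce_n`
// consecutive samples back inside +/- exit_band of the baseline frozen at
// opening. Shoulder excursions are absorbed into the adjacent dip event
// rather than reported separately.
//
// The state travels as an R list between calls; events are emitted with
// 0-based global sample indices and post-processed (widths, flags,
// absorbance) on the R side.

struct DetState {
  long long g;          // global index of next sample
  int phase;            // 0 = collecting init buffer, 1 = running
  NumericVector init_buf;   // smoothed samples awaiting baseline init
  NumericVector init_raw;   // matching raw samples (saturation checks)
  int init_count;
  double b;             // baseline estimate
  NumericVector ring;   // raw-sample ring buffer for the causal MA
  int ring_pos, ring_count;
  double ring_sum;
  bool in_event;
  long long ev_start, ev_imin, ev_end_cand;
  double ev_bfrozen, ev_vmin;
  bool ev_below, ev_sat;
  int debounce;
};

struct Emitted {
  std::vector<double> start, imin, end, vmin, bfrozen;
  std::vector<int> below, sat, open;
};

static double median_of(NumericVector v, int n) {
  std::vector<double> x(v.begin(), v.begin() + n);
  std::sort(x.begin(), x.end());
  if (n % 2 == 1) return x[n / 2];
  return 0.5 * (x[n / 2 - 1] + x[n / 2]);
}

static void emit(Emitted &out, const DetState &s, long long end_idx, bool open) {
  out.start.push_back((double)s.ev_start);
  out.imin.push_back((double)s.ev_imin);
  out.end.push_back((double)end_idx);
  out.vmin.push_back(s.ev_vmin);
  out.bfrozen.push_back(s.ev_bfrozen);
  out.below.push_back(s.ev_below ? 1 : 0);
  out.sat.push_back(s.ev_sat ? 1 : 0);
  out.open.push_back(open ? 1 : 0);
}

static void process_sample(DetState &s, double y, double x_raw, long long g,
                           double alpha, double enter_delta,
                           double shoulder_delta, double exit_band,
                           int debounce_n, double v_sat, Emitted &out) {
  if (!s.in_event) {
    if (y < s.b - enter_delta || y > s.b + shoulder_delta) {
      s.in_event = true;
      s.ev_start = g;
      s.ev_bfrozen = s.b;
      s.ev_vmin = y;
      s.ev_imin = g;
      s.ev_below = (y < s.b - enter_delta);
      s.ev_sat = (x_raw >= v_sat - 1e-9);
      s.debounce = 0;
    } else {
      s.b += alpha * (y - s.b);
    }
  } else {
    if (y < s.ev_vmin) { s.ev_vmin = y; s.ev_imin = g; }  // earliest min wins ties
    if (y < s.ev_bfrozen - enter_delta) s.ev_below = true;
    if (x_raw >= v_sat - 1e-9) s.ev_sat = true;
    if (std::fabs(y - s.ev_bfrozen) <= exit_band) {
      if (s.debounce == 0) s.ev_end_cand = g;
      s.debounce++;
      if (s.debounce >= debounce_n) {
        emit(out, s, s.ev_end_cand, false);
        s.in_event = false;
        s.debounce = 0;
        s.b += alpha * (y - s.b);
      }
    } else {
      s.debounce = 0;
    }
  }
}

static List state_to_list(const DetState &s) {
  return List::create(
    _["g"] = (double)s.g, _["phase"] = s.phase,
    _["init_buf"] = s.init_buf, _["init_raw"] = s.init_raw,
    _["init_count"] = s.init_count,
    _["b"] = s.b, _["ring"] = s.ring, _["ring_pos"] = s.ring_pos,
    _["ring_count"] = s.ring_count, _["ring_sum"] = s.ring_sum,
    _["in_event"] = s.in_event, _["ev_start"] = (double)s.ev_start,
    _["ev_imin"] = (double)s.ev_imin, _["ev_end_cand"] = (double)s.ev_end_cand,
    _["ev_bfrozen"] = s.ev_bfrozen, _["ev_vmin"] = s.ev_vmin,
    _["ev_below"] = s.ev_below, _["ev_sat"] = s.ev_sat,
    _["debounce"] = s.debounce);
}

static DetState state_from_list(List st) {
  DetState s;
  s.g = (long long)as<double>(st["g"]);
  s.phase = as<int>(st["phase"]);
  s.init_buf = as<NumericVector>(st["init_buf"]);
  s.init_raw = as<NumericVector>(st["init_raw"]);
  s.init_count = as<int>(st["init_count"]);
  s.b = as<double>(st["b"]);
  s.ring = as<NumericVector>(st["ring"]);
  s.ring_pos = as<int>(st["ring_pos"]);
  s.ring_count = as<int>(st["ring_count"]);
  s.ring_sum = as<double>(st["ring_sum"]);
  s.in_event = as<bool>(st["in_event"]);
  s.ev_start = (long long)as<double>(st["ev_start"]);
  s.ev_imin = (long long)as<double>(st["ev_imin"]);
  s.ev_end_cand = (long long)as<double>(st["ev_end_cand"]);
  s.ev_bfrozen = as<double>(st["ev_bfrozen"]);
  s.ev_vmin = as<double>(st["ev_vmin"]);
  s.ev_below = as<bool>(st["ev_below"]);
  s.ev_sat = as<bool>(st["ev_sat"]);
  s.debounce = as<int>(st["debounce"]);
  return s;
}

static List emitted_to_list(const Emitted &out) {
  return List::create(
    _["i_start"] = wrap(out.start), _["i_min"] = wrap(out.imin),
    _["i_end"] = wrap(out.end), _["v_min"] = wrap(out.vmin),
    _["baseline"] = wrap(out.bfrozen), _["below"] = wrap(out.below),
    _["saturated"] = wrap(out.sat), _["forced_open"] = wrap(out.open));
}

// [[Rcpp::export]]
List cpp_detector_init(int smooth_n, int init_n) {
  DetState s;
  s.g = 0; s.phase = 0;
  s.init_buf = NumericVector(init_n);
  s.init_raw = NumericVector(init_n);
  s.init_count = 0;
  s.b = 0.0;
  s.ring = NumericVector(smooth_n);
  s.ring_pos = 0; s.ring_count = 0; s.ring_sum = 0.0;
  s.in_event = false;
  s.ev_start = s.ev_imin = s.ev_end_cand = 0;
  s.ev_bfrozen = s.ev_vmin = 0.0;
  s.ev_below = s.ev_sat = false;
  s.debounce = 0;
  return state_to_list(s);
}

// [[Rcpp::export]]
List cpp_detector_feed(NumericVector samples, List state, double alpha,
                       double enter_delta, double shoulder_delta,
                       double exit_band, int debounce_n, double v_sat) {
  DetState s = state_from_list(state);
  Emitted out;
  int smooth_n = s.ring.size();
  int init_n = s.init_buf.size();
  for (int k = 0; k < samples.size(); ++k) {
    double x = samples[k];
    if (s.ring_count == smooth_n) {
      s.ring_sum -= s.ring[s.ring_pos];
    } else {
      s.ring_count++;
    }
    s.ring[s.ring_pos] = x;
    s.ring_sum += x;
    s.ring_pos = (s.ring_pos + 1) % smooth_n;
    double y = s.ring_sum / s.ring_count;
    if (s.phase == 0) {
      s.init_buf[s.init_count] = y;
      s.init_raw[s.init_count] = x;
      s.init_count++;
      if (s.init_count == init_n) {
        s.b = median_of(s.init_buf, s.init_count);
        for (int j = 0; j < s.init_count; ++j) {
          process_sample(s, s.init_buf[j], s.init_raw[j],
                         s.g - (long long)(s.init_count - 1 - j),
                         alpha, enter_delta, shoulder_delta, exit_band,
                         debounce_n, v_sat, out);
        }
        s.phase = 1;
      }
    } else {
      process_sample(s, y, x, s.g, alpha, enter_delta, shoulder_delta,
                     exit_band, debounce_n, v_sat, out);
    }
    s.g++;
  }
  return List::create(_["events"] = emitted_to_list(out),
                      _["state"] = state_to_list(s));
}

// [[Rcpp::export]]
List cpp_detector_finish(List state, double alpha, double enter_delta,
                         double shoulder_delta, double exit_band,
                         int debounce_n, double v_sat) {
  DetState s = state_from_list(state);
  Emitted out;
  if (s.phase == 0 && s.init_count > 0) {
    s.b = median_of(s.init_buf, s.init_count);
    for (int j = 0; j < s.init_count; ++j) {
      process_sample(s, s.init_buf[j], s.init_raw[j],
                     s.g - (long long)(s.init_count - j),
                     alpha, enter_delta, shoulder_delta, exit_band,
                     debounce_n, v_sat, out);
    }
    s.phase = 1;
  }
  if (s.in_event) {
    emit(out, s, s.g - 1, true);
    s.in_event = false;
  }
  return List::create(_["events"] = emitted_to_list(out),
                      _["state"] = state_to_list(s));
}
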