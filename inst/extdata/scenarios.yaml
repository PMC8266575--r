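# Simulation scenarios: each encodes the fitted conformational ensemble of a
# G4-forming sequence as reported by force-ramp measurements (peak unfolding
# forces and per-peak fractions of cycles), with the transition distance
# fixed at 1.0 nm and k_unfold solved from the modal force at the protocol
# loading rate. step_nt values labelled full/gvbq_* follow the sequence
# topology; the "weak" ~16 pN species has no assigned topology and its
# step_nt (10 nt) is a synthetic choice.
protocol:
  f_start: 1
  f_end: 60
  loading_rate: 2
  hold_force: 1
  hold_time: 30
  kBT: 4.11
polymer:
  persistence_length_nm: 0.8
  contour_per_nt_nm: 0.56
  folded_extent_nm: 2.0
  kBT_pN_nm: 4.11
noise:
  sigma_step_nm: 0.6
  sigma_bead_nm: 1.0
  trace_rate_hz: 100
scenarios:
  T30695:
    sequence: T30695
    states:
      - {label: weak, peak_pN: 16, step_nt: 10, weight: 0.10}
      - {label: full, peak_pN: 55, step_nt: 15, weight: 0.85}
    w_unfolded: 0.05
    kinetics: {p_st: 0.75, k_fold: 0.03}
  TB-1:
    sequence: TB-1
    states:
      - {label: gvbq_5p, peak_pN: 22, step_nt: 14, weight: 0.62}
      - {label: intermediate, peak_pN: 36, step_nt: 13, weight: 0.25}
      - {label: full, peak_pN: 47, step_nt: 16, weight: 0.07}
    w_unfolded: 0.06
    kinetics: {p_st: 0.94, k_fold: 0.11}
  TB-2:
    sequence: TB-2
    states:
      - {label: weak, peak_pN: 16, step_nt: 10, weight: 0.10}
      - {label: full, peak_pN: 55, step_nt: 16, weight: 0.85}
    w_unfolded: 0.05
    kinetics: {p_st: 0.69, k_fold: 0.02}
  TB-8:
    sequence: TB-8
    states:
      - {label: gvbq_3p, peak_pN: 31, step_nt: 14, weight: 0.33}
      - {label: full, peak_pN: 46, step_nt: 16, weight: 0.63}
    w_unfolded: 0.04
    kinetics: {p_st: 0.96, k_fold: 0.10}
  TB-1+GRPC:
    sequence: TB-1
    states:
      - {label: intermediate, peak_pN: 33, step_nt: 13, weight: 0.35}
      - {label: grpc_filled, peak_pN: 53, step_nt: 16, weight: 0.55}
    w_unfolded: 0.10
  T3B-1:
    sequence: T3B-1
    states:
      - {label: gvbq_5p, peak_pN: 20, step_nt: 14, weight: 0.60}
      - {label: intermediate, peak_pN: 36, step_nt: 13, weight: 0.30}
    w_unfolded: 0.10
    kinetics: {p_st: 0.90, k_fold: 0.10}
  T3B-1+GRPC:
    sequence: T3B-1
    states:
      - {label: intermediate, peak_pN: 40, step_nt: 13, weight: 0.40}
      - {label: grpc_filled, peak_pN: 55, step_nt: 16, weight: 0.50}
    w_unfolded: 0.10
  T3B-8:
    sequence: T3B-8
    states:
      - {label: gvbq_3p, peak_pN: 20, step_nt: 14, weight: 0.60}
      - {label: intermediate, peak_pN: 36, step_nt: 13, weight: 0.30}
    w_unfolded: 0.10
    kinetics: {p_st: 0.90, k_fold: 0.10}
  T2B-3:
    sequence: T2B-3
    states:
      - {label: weak, peak_pN: 16, step_nt: 10, weight: 0.30}
      - {label: intermediate, peak_pN: 36, step_nt: 13, weight: 0.30}
      - {label: full, peak_pN: 55, step_nt: 17, weight: 0.25}
    w_unfolded: 0.15
    kinetics: {p_st: 0.79, k_fold: 0.03}
melting_scenarios:
  top_tetrad: {tm_C: 48, width_C: 3}
  bottom_tetrad: {tm_C: 44, width_C: 3}
  middle_tetrad: {tm_C: 36, width_C: 3}
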