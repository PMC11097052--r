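# Parameter banks per detector: "default" as published for the original
# sensor position, "optimized" as tuned for the wrist. Thresholds are in g.
paraschiv2019:
  default:            # lower-back GSDB; the GSDC variant used th = 0.15
    th: 0.1
  optimized:          # wrist
    th: 0.35
paraschiv2020:        # data-adaptive threshold; not tuned, banks identical
  default:
    n_smooth_iters: 2
    adapt_quantile: 0.1
    adapt_floor_g: 0.05
  optimized:
    n_smooth_iters: 2
    adapt_quantile: 0.1
    adapt_floor_g: 0.05
iluz:
  default:
    activity_thres: 0.01
    min_bout_length: 5
    template_len: 0.5
    cm_norm_thres: 0.4
  optimized:
    activity_thres: 0.04
    min_bout_length: 10
    template_len: 1
    cm_norm_thres: 2.5
gu:
  default:
    verisense_k: 3
    sim_thres: -0.5
    cont_thres: 4
    mag_thres: 1.2
  optimized:
    verisense_k: 2
    sim_thres: -0.8
    cont_thres: 4
    mag_thres: 1.2
karas:
  default:
    sim_MIN: 0.85
    dur_MIN: 0.8
    dur_MAX: 1.4
    ptp_r_MIN: 0.2
    ptp_r_MAX: 2.0
    mean_abs_diff_med_p_MAX: 0.5
    mean_abs_diff_med_t_MAX: 0.2
    mean_abs_diff_dur_MAX: 0.2
  optimized:
    sim_MIN: 0.3
    dur_MIN: 0.2
    dur_MAX: 3.0
    ptp_r_MIN: 0.2
    ptp_r_MAX: 3.0
    mean_abs_diff_med_p_MAX: 0.5
    mean_abs_diff_med_t_MAX: 0.5
    mean_abs_diff_dur_MAX: 0.5
hickey:
  default:
    ThresholdStill: 0.2
    ThresholdUpright: -0.5
  optimized:
    ThresholdStill: 0.2
    ThresholdUpright: -0.5
kheirkhahan:
  default:
    walking_threshold: 0.75
  optimized:
    walking_threshold: 0.6
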