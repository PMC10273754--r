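# Default synthetic-cohort design: four amyloid-PET staged groups.
# Backbones come from the hub-concentrated ring family; n_sources and
# ring_prob are set per group so that thresholded-network global-efficiency
# AUCs follow a decrease -> increase -> decrease trajectory across the
# amyloid-positive groups (CN+ below CN-, MCI+ above CN+, AD+ lowest).
# All values here are synthetic design parameters, not estimates from any
# real cohort. n_sources scales with n_regions via source_frac.
n_regions: 200
n_timepoints: 200
jitter_sd: 0.1
ar1: 0.3
tr_seconds: 3
groups:
  - name: CN_Abeta_neg
    n_subjects: 81
    noise_sd: 1.0
    backbone: {family: hub_ring, source_frac: 1.00, ring_prob: 0.2, strength: 0.28, lags: [1, 2]}
  - name: CN_Abeta_pos
    n_subjects: 36
    noise_sd: 1.0
    backbone: {family: hub_ring, source_frac: 0.40, ring_prob: 0.2, strength: 0.28, lags: [1, 2]}
  - name: MCI_Abeta_pos
    n_subjects: 31
    noise_sd: 1.0
    backbone: {family: hub_ring, source_frac: 1.00, ring_prob: 0.9, strength: 0.28, lags: [1, 2]}
  - name: AD_Abeta_pos
    n_subjects: 18
    noise_sd: 1.0
    backbone: {family: hub_ring, source_frac: 0.17, ring_prob: 0.0, strength: 0.28, lags: [1, 2]}
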