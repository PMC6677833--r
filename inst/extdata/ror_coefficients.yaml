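# Subtype-correlation risk-of-recurrence coefficients (ROR-S, Parker et al.
# 2009, J Clin Oncol 27:1160): risk = sum_k coef_k * cor(sample, centroid_k)
# over the intrinsic-subtype centroids.  Edit to match whatever centroid set
# is supplied; names must equal the centroid column names.
coefficients:
  Basal: 0.05
  Her2: 0.12
  LumA: -0.34
  LumB: 0.23
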