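# Microarray-adapted 21-gene recurrence-score model.
# Gene groups, group weights, group coefficients and RT-PCR group floors as
# published for the 21-gene assay (Paik et al. 2004, N Engl J Med 351:2817;
# Fan et al. 2006, N Engl J Med 355:560).  Gene symbols are HGNC; STK15 =
# AURKA, survivin = BIRC5, CTSL2 = cathepsin V.  The floors ("threshold")
# are on the RT-PCR reference-normalized scale and are only applied on
# request.  CD68 is read from its pinned array probe when probe-level data
# are collapsed.
housekeeping: [ACTB, GAPDH, GUSB, RPLP0, TFRC]
groups:
  her2:
    coefficient: 0.47
    threshold: 8.0
    genes: {GRB7: 0.9, ERBB2: 0.1}
  estrogen:
    coefficient: -0.34
    genes: {ESR1: 0.8, PGR: 1.2, BCL2: 1.0, SCUBE2: 1.0}
  proliferation:
    coefficient: 1.04
    threshold: 6.5
    genes: {BIRC5: 1.0, MKI67: 1.0, MYBL2: 1.0, CCNB1: 1.0, AURKA: 1.0}
  invasion:
    coefficient: 0.10
    genes: {MMP11: 1.0, CTSL2: 1.0}
  cd68:
    coefficient: 0.05
    genes: {CD68: 1.0}
  gstm1:
    coefficient: -0.08
    genes: {GSTM1: 1.0}
  bag1:
    coefficient: -0.07
    genes: {BAG1: 1.0}
pinned_probes: {CD68: 203507_at}
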