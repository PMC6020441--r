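panel_name: actionable_cancer_predisposition
groups:
  - name: high_risk_HBOC
    risk_tier: high
    genes: [BRCA1, BRCA2, PALB2]
  - name: LS_MMR
    risk_tier: high
    genes: [MLH1, MSH2, MSH6, PMS2]
  - name: other_high_risk
    risk_tier: high
    genes: [TP53, CDKN2A, STK11, APC]
  - name: moderate_HRR_BC
    risk_tier: moderate
    genes: [ATM, BARD1, CHEK2, NBN]
  - name: ICR_other
    risk_tier: other
    genes: [MRE11A, RAD50, BRIP1]
  # aggregate groups for the pooled analyses; tier `other` so the
  # high/moderate partition above stays disjoint
  - name: high_risk_all
    risk_tier: other
    genes: [BRCA1, BRCA2, PALB2, MLH1, MSH2, MSH6, PMS2, TP53, CDKN2A, STK11, APC]
  - name: high_plus_moderate
    risk_tier: other
    genes: [BRCA1, BRCA2, PALB2, MLH1, MSH2, MSH6, PMS2, TP53, CDKN2A, STK11, APC, ATM, BARD1, CHEK2, NBN]
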