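# Exclusion of a brand-name or biosimilar antipsoriatic, 2021-2022 US inputs.
# One share group; TNF inhibitors carry a lower discontinuation range than
# the other agents, so outcome models attach per medication.
name: psoriasis
population:
  total: 333300000
  segments:
    - name: employer private
      percent: 48.5
    - name: small group private
      percent: 6.1
    - name: Medicare Part D
      percent: 14.7
formularies:
  - name: CVS
    market_share: 0.33
  - name: ESI
    market_share: 0.24
indication:
  name: psoriasis
  prevalence:
    low: 0.015
    high: 0.03
  calibration_factor: 1.0
share_groups:
  - group_id: antipsoriatics
    medications:
      - {brand_name: Humira, generic_name: adalimumab, share_percent: 38.92, outcome_model: tnf}
      - {brand_name: Enbrel, generic_name: etanercept, share_percent: 13.18, outcome_model: tnf}
      - {brand_name: Cimzia, generic_name: certolizumab, share_percent: 2.50, outcome_model: tnf}
      - {brand_name: Simponi, generic_name: golimumab, share_percent: 1.41, outcome_model: tnf}
      - {brand_name: Remicade, generic_name: infliximab, share_percent: 0.52, outcome_model: tnf}
      - {brand_name: Inflectra, generic_name: infliximab, share_percent: 0.30, outcome_model: tnf}
      - {brand_name: Renflexis, generic_name: infliximab, share_percent: 0.03, outcome_model: tnf}
      - {brand_name: Avsola, generic_name: infliximab, share_percent: 0.02, outcome_model: tnf}
      - {brand_name: Infliximab, generic_name: infliximab, share_percent: 0.02, outcome_model: tnf}
      - {brand_name: Otezla, generic_name: apremilast, share_percent: 8.55, outcome_model: other}
      - brand_name: Cosentyx
        generic_name: secukinumab
        share_percent: 7.30
        outcome_model: other
        note: >-
          Reference table prints "Cosentyx (ustekinumab)"; Cosentyx is
          secukinumab (ustekinumab is Stelara).
      - {brand_name: Stelara, generic_name: ustekinumab, share_percent: 6.38, outcome_model: other}
      - {brand_name: Taltz, generic_name: ixekizumab, share_percent: 6.17, outcome_model: other}
      - {brand_name: Xeljanz, generic_name: tofacitinib, share_percent: 5.24, outcome_model: other}
      - {brand_name: Tremfya, generic_name: guselkumab, share_percent: 3.46, outcome_model: other}
      - {brand_name: Rinvoq, generic_name: upadacitinib, share_percent: 3.23, outcome_model: other}
      - {brand_name: Skyrizi, generic_name: risankizumab, share_percent: 2.63, outcome_model: other}
      - {brand_name: Siliq, generic_name: brodalumab, share_percent: 0.07, outcome_model: other}
      - {brand_name: Ilumya, generic_name: tildrakizumab, share_percent: 0.06, outcome_model: other}
outcome_models:
  - id: tnf                   # forced switching between TNF inhibitors
    discontinuation:
      low: 0.06
      high: 0.09
    adverse_event_rule:
      type: flat_rate
      rate:
        low: 0.15
        high: 0.35
  - id: other                 # cross-class nonmedical-switching meta-analysis
    discontinuation:
      low: 0.09
      high: 0.19
    adverse_event_rule:
      type: flat_rate
      rate:
        low: 0.15
        high: 0.35
output_unit: thousands
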