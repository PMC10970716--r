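# Exclusion of a brand-name anticoagulant (AFib/VTE), 2021-2022 US inputs.
name: anticoagulants
population:
  total: 333300000            # 2022 US Census estimate
  segments:
    - name: employer private
      percent: 48.5
    - name: small group private
      percent: 6.1
    - name: Medicare Part D
      percent: 14.7
formularies:
  - name: CVS                 # CVS Caremark Performance Standard Control
    market_share: 0.33
  - name: ESI                 # Express Scripts National Preferred
    market_share: 0.24
indication:
  name: AFib/VTE
  # Combined bound-wise: atrial fibrillation 0.010-0.029 plus venous
  # thromboembolism 0.004-0.005.
  prevalence:
    low: 0.014
    high: 0.034
  calibration_factor: 1.0
share_groups:
  - group_id: anticoagulants
    medications:
      - brand_name: Eliquis
        generic_name: apixaban
        share_percent: 68.88
        outcome_model: anticoagulant
      - brand_name: Xarelto
        generic_name: rivaroxaban
        share_percent: 29.76
        outcome_model: anticoagulant
      - brand_name: Pradaxa
        generic_name: dabigatran
        share_percent: 1.31
        outcome_model: anticoagulant
      - brand_name: Savaysa
        generic_name: edoxaban
        share_percent: 0.06
        outcome_model: anticoagulant
outcome_models:
  - id: anticoagulant
    discontinuation:          # all-anticoagulant discontinuation on exclusion
      low: 0.17
      high: 0.30
    adverse_event_rule:
      type: coupled_compound
      event_given_discontinuation:   # serious cardiovascular event risk
        low: 0.45
        high: 0.85
      event_given_switch:            # adverse event after switching agents
        low: 0.02
        high: 0.10
output_unit: thousands
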