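# Classical six-domain SOFA threshold system (Vincent et al., Intensive Care
# Med 1996, as operationalised for electronic records: the cardiovascular
# domain is banded on the noradrenaline-equivalent infusion rate).
# All thresholds are configuration: the scoring engine is threshold-agnostic.
system: SOFA-1
version: "1996-classical/nee-1.0"
unit_conversions:
  bilirubin:  {umol/L: 1.0, mg/dL: 17.1}
  creatinine: {umol/L: 1.0, mg/dL: 88.4}
  platelets:  {10^9/L: 1.0, 10^3/uL: 1.0}
  map:        {mmHg: 1.0}
  urine_output: {mL: 1.0}
  pao2:       {mmHg: 1.0, kPa: 7.50062}
  fio2:       {fraction: 1.0, percent: 0.01}
  spo2:       {percent: 1.0, fraction: 100.0}
  gcs_total:  {score: 1.0}
  gcs_eye:    {score: 1.0}
  gcs_verbal: {score: 1.0}
  gcs_motor:  {score: 1.0}
# multipliers onto a noradrenaline-equivalent rate in ug/kg/min
# (vasopressin rates are U/min; angiotensin II ng/kg/min x 0.01 -> factor 10
# documented per drug in the package manual)
nee_factors:
  noradrenaline: 1.0
  adrenaline: 1.0
  dopamine: 0.01
  phenylephrine: 0.1
  metaraminol: 0.125
  vasopressin: 2.5
  angiotensin_2: 10.0
  dobutamine: 0.0
  milrinone: 0.0
# raw aggregate values assumed when a domain is unmeasured on day 1
normal_values:
  pf_ratio: 450
  sf_ratio: 470
  platelets: 250
  bilirubin: 8
  map: 80
  gcs: 15
  creatinine: 70
  urine_output: 1500
  nee: 0
domains:
  - name: respiration
    rules:
      - points: 4
        when: {all_of: [{var: pf_ratio, op: "<", value: 100}, {flag: resp_support}]}
      - points: 3
        when: {all_of: [{var: pf_ratio, op: "<", value: 200}, {flag: resp_support}]}
      - points: 2
        when: {var: pf_ratio, op: "<", value: 300}
      - points: 1
        when: {var: pf_ratio, op: "<", value: 400}
  - name: coagulation
    rules:
      - points: 4
        when: {var: platelets, op: "<", value: 20}
      - points: 3
        when: {var: platelets, op: "<", value: 50}
      - points: 2
        when: {var: platelets, op: "<", value: 100}
      - points: 1
        when: {var: platelets, op: "<", value: 150}
  - name: liver
    rules:
      - points: 4
        when: {var: bilirubin, op: ">", value: 204}
      - points: 3
        when: {var: bilirubin, op: ">=", value: 102}
      - points: 2
        when: {var: bilirubin, op: ">=", value: 33}
      - points: 1
        when: {var: bilirubin, op: ">=", value: 20}
  - name: cardiovascular
    rules:
      - points: 4
        when: {var: nee, op: ">", value: 0.1}
      - points: 3
        when: {var: nee, op: ">", value: 0}
      - points: 2
        when: {flag: inotrope}
      - points: 1
        when: {var: map, op: "<", value: 70}
  - name: brain
    rules:
      - points: 4
        when: {var: gcs, op: "<", value: 6}
      - points: 3
        when: {var: gcs, op: "<", value: 10}
      - points: 2
        when: {var: gcs, op: "<", value: 13}
      - points: 1
        when: {var: gcs, op: "<", value: 15}
  - name: renal
    rules:
      - points: 4
        when: {any_of: [{var: creatinine, op: ">", value: 440},
                        {var: urine_output, op: "<", value: 200}]}
      - points: 3
        when: {any_of: [{var: creatinine, op: ">=", value: 300},
                        {var: urine_output, op: "<", value: 500}]}
      - points: 2
        when: {var: creatinine, op: ">=", value: 171}
      - points: 1
        when: {var: creatinine, op: ">=", value: 110}
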