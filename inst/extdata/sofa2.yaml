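# Recalibrated six-domain SOFA threshold system ("SOFA-2", 2025 update).
# Structural changes relative to the classical system: pulse-oximetric
# S/F ratio accepted alongside P/F, ECMO scores in the respiratory and
# cardiovascular domains, RRT scores in the renal domain,
# delirium-requiring-medication scores in the brain domain, and the
# cardiovascular domain is banded on higher noradrenaline-equivalent rates.
# Numeric cut-offs below are editable configuration defaults chosen to
# reproduce the published recalibration's structure; deployments scoring
# real patients should verify each band against the primary SOFA-2
# publication before use.
system: SOFA-2
version: "2025-recalibration/defaults-1.0"
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
        when: {any_of: [{flag: ecmo},
                        {all_of: [{any_of: [{var: pf_ratio, op: "<", value: 75},
                                            {var: sf_ratio, op: "<", value: 90}]},
                                  {flag: resp_support}]}]}
      - points: 3
        when: {all_of: [{any_of: [{var: pf_ratio, op: "<", value: 150},
                                  {var: sf_ratio, op: "<", value: 180}]},
                        {flag: resp_support}]}
      - points: 2
        when: {any_of: [{var: pf_ratio, op: "<", value: 220},
                        {var: sf_ratio, op: "<", value: 270}]}
      - points: 1
        when: {any_of: [{var: pf_ratio, op: "<", value: 330},
                        {var: sf_ratio, op: "<", value: 370}]}
  - name: coagulation
    rules:
      - points: 4
        when: {var: platelets, op: "<", value: 20}
      - points: 3
        when: {var: platelets, op: "<", value: 50}
      - points: 2
        when: {var: platelets, op: "<", value: 80}
      - points: 1
        when: {var: platelets, op: "<", value: 120}
  - name: liver
    rules:
      - points: 4
        when: {var: bilirubin, op: ">", value: 204}
      - points: 3
        when: {var: bilirubin, op: ">=", value: 102}
      - points: 2
        when: {var: bilirubin, op: ">=", value: 40}
      - points: 1
        when: {var: bilirubin, op: ">=", value: 23}
  - name: cardiovascular
    rules:
      - points: 4
        when: {any_of: [{var: nee, op: ">", value: 0.4},
                        {all_of: [{flag: ecmo}, {flag: vasopressor}]}]}
      - points: 3
        when: {var: nee, op: ">", value: 0.2}
      - points: 2
        when: {any_of: [{var: nee, op: ">", value: 0}, {flag: inotrope}]}
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
        when: {any_of: [{var: gcs, op: "<", value: 15},
                        {flag: delirium_medication}]}
  - name: renal
    rules:
      - points: 4
        when: {any_of: [{flag: rrt},
                        {var: creatinine, op: ">", value: 440},
                        {var: urine_output, op: "<", value: 200}]}
      - points: 3
        when: {any_of: [{var: creatinine, op: ">=", value: 300},
                        {var: urine_output, op: "<", value: 500}]}
      - points: 2
        when: {var: creatinine, op: ">=", value: 180}
      - points: 1
        when: {var: creatinine, op: ">=", value: 120}
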