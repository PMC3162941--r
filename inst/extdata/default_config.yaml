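# Default ICU monitoring configuration.
#
# Input membership functions (piecewise-linear breakpoints, specialist-
# elicited by the direct method), the six-rule Mamdani base, and the
# pre-diagnosis output situations supported on the bands
# <2.5 / 2.5-4.5 / 4-6 / 5.5-8 / >8 of the [0,10] score.
variables:
  - name: MBP
    units: mmHg
    domain: [0, 200]
    sets:
      - name: low
        points: [[0, 1], [60, 1], [80, 0]]
      - name: normal
        points: [[75, 0], [105, 1], [130, 0]]
      - name: high
        points: [[126, 0], [138.7, 1], [200, 1]]
  - name: SpO2
    units: "%"
    domain: [0, 100]
    sets:
      - name: low
        points: [[0, 1], [90, 1], [94, 0]]
      - name: normal
        points: [[89.2, 0], [96.2, 1], [100, 0]]
output:
  name: prediagnosis
  units: score
  domain: [0, 10]
  sets:
    - name: instability
      points: [[0, 1], [1.25, 1], [2.5, 0]]
    - name: low_MBP
      points: [[2.5, 0], [3.5, 1], [4.5, 0]]
    - name: hypoxemia
      points: [[4, 0], [5, 1], [6, 0]]
    - name: stable
      points: [[5.5, 0], [6.75, 1], [8, 0]]
    - name: high_MBP
      points: [[8, 0], [9, 1], [10, 1]]
rules:
  - id: 1
    antecedents:
      - {variable: MBP, term: low}
      - {variable: SpO2, term: low}
    consequent: instability
    message: "The patient's vital signs are altered"
    urgency: high
  - id: 2
    antecedents:
      - {variable: MBP, term: low}
      - {variable: SpO2, term: normal}
    consequent: low_MBP
    message: "The patient's blood pressure is low"
    urgency: low
  - id: 3
    antecedents:
      - {variable: MBP, term: normal}
      - {variable: SpO2, term: low}
    consequent: hypoxemia
    message: "Patient with hypoxemia - abnormal deficiency of oxygen concentration in arterial blood"
    urgency: high
  - id: 4
    antecedents:
      - {variable: MBP, term: normal}
      - {variable: SpO2, term: normal}
    consequent: stable
    message: "No alert"
    urgency: none
  - id: 5
    antecedents:
      - {variable: MBP, term: high}
      - {variable: SpO2, term: low}
    consequent: instability
    message: "The patient's vital signs are altered"
    urgency: medium
  - id: 6
    antecedents:
      - {variable: MBP, term: high}
      - {variable: SpO2, term: normal}
    consequent: high_MBP
    message: "The patient's blood pressure is high"
    urgency: low
monitoring:
  debounce_seconds: 0
  stale_gap_seconds: 30
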