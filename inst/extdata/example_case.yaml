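# Worked example: 42-year-old referred for poor responses to psychotropics
# and pain killers. Two medications, both guideline-covered, both with
# adequate trials and unexpected poor efficacy.
patient:
  id: example-001
  age: 42
  sex: male
  summary: depression, anxiety, insomnia, chronic lower back pain
medications:
  - name: codeine
    status: current
    dose: 30 mg up to four times daily
    duration: 3 months
    trial_adequate: "yes"
    outcome: poor_efficacy
  - name: clomipramine
    status: current
    dose: 150 mg daily
    duration: 12 weeks
    trial_adequate: "yes"
    outcome: poor_efficacy
comedications: []
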