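# controlled vocabulary for the study monitors
data_types: [SpO2, HR, PR, SpO2Alarm, SpO2Med]
tokens: ['NaN', '^^', '5']
sq_types:
  grade:
    domain: [0, 1, 2, 3]
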