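# pulse oximeter pod integrated with the bedside monitor, numerics at 0.5 Hz
device_id: oximeter
native_rate: 0.5
mapping:
  spo2: SpO2
  pr: PR
  alarm: SpO2Alarm
tokens: ['NaN', '^^', '5']
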