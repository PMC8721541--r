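duration_h: 48.0
bolus_lead_min: 15.0
ht_grams: 16.0
ht_threshold: 65.0
ht_lockout_min: 30.0
controller_period_min: 5.0
meals:
- day: 1.0
  time: '07:00'
  grams: 45.0
  announced: yes
- day: 1.0
  time: '12:30'
  grams: 70.0
  announced: yes
- day: 1.0
  time: '16:00'
  grams: 20.0
  announced: yes
- day: 1.0
  time: '19:00'
  grams: 60.0
  announced: yes
- day: 1.0
  time: '22:00'
  grams: 15.0
  announced: yes
- day: 2.0
  time: '07:00'
  grams: 45.0
  announced: yes
- day: 2.0
  time: '12:30'
  grams: 70.0
  announced: yes
- day: 2.0
  time: '16:00'
  grams: 20.0
  announced: yes
- day: 2.0
  time: '19:00'
  grams: 60.0
  announced: yes
- day: 2.0
  time: '22:00'
  grams: 15.0
  announced: yes
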