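name: closing3am_lockout1am
start_date: '2017-01-01'
overrides:
  venue_closing_hour: 3.0
  lockout_hour: 1.0
  bottle_shop_closing_hour: 22.0
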