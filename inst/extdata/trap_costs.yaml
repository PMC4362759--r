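# Indicative trap hardware prices ($US) and field times (minutes) for the
# trap models compared in the cost analysis.  Labour is costed separately
# at a daily contract rate (default $NZ300 per 480-minute day).
traps:
  - model: Sentinel
    type: single
    price: 24.00
    setup_time: 5
    check_time: 2
  - model: Goodnature A12/A24
    type: multi
    price: 140.00
    setup_time: 5
    check_time: 3
  - model: Victor snap-back
    type: single
    price: 6.30
    setup_time: 4
    check_time: 2
  - model: DOC 150 + tunnel
    type: single
    price: 38.00
    setup_time: 3
    check_time: 3
labour:
  daily_rate: 300      # $NZ per day
  minutes_per_day: 480
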