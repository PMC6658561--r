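# Default five-test PTSD-like battery: lowest 20% of risk-assessment time,
# startle latency and percent pre-pulse inhibition; upper 20% of home-cage
# activity (non-active phase) and percent of marbles buried.
percentile: 0.20
min_extreme_tests: 3
tests:
  - name: risk_assessment
    direction: low
  - name: startle_latency
    direction: low
  - name: ppi
    direction: low
  - name: homecage_activity
    direction: high
  - name: marbles_buried
    direction: high
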