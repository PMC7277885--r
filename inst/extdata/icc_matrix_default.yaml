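# Default Index of Caring Complexity matrix: clinical-instability band
# (rows) x care-dependence level (columns) -> complexity class.
# Hospitals can localize the mapping; any replacement must stay monotone
# non-decreasing along both axes (validated on load).
stable: {low: Low, average: Medium, high: High}
unstable: {low: Medium, average: Medium, high: High}
critical: {low: High, average: High, high: High}
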