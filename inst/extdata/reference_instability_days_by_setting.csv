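setting,stable,unstable,critical
sub_intensive,31,35,13
high,123,55,7
medium,1888,269,140
low,205,67,55
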