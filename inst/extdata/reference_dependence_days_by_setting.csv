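setting,low,average,high
sub_intensive,30,44,5
high,59,117,9
medium,1289,855,153
low,58,182,83
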