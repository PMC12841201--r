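gene	brainstem_100	brainstem_250	forebrain_100	forebrain_250
Aldh7a1	.085	.268	.636	.571
Cept1	.996	.963	.771	.821
Slc44a1	.913	.998	.521	.962
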