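sample_id	status
sample0001	case
sample0002	control
sample0003	control
sample0004	control
sample0005	control
sample0006	control
sample0007	control
sample0008	control
sample0009	case
sample0010	case
sample0011	control
sample0012	control
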