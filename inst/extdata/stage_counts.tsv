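stage	count
class_frameshift	326
class_intronic	40
class_nonframeshift	47
class_missense	1486
class_canonical_splicing	120
class_start_loss	5
class_stop_gain	333
class_stop_loss	5
class_synonymous	37
class_utr	4
stated_total	2404
prioritized_total	185
prioritized_intronic	18
prioritized_missense	35
prioritized_canonical	112
prioritized_stop_gain	12
prioritized_synonymous	8
prioritized_both_arms	132
ncsv_positive_total	49
splicing_total	169
ncsv_new	17
ncsv_previous	32
validated_positive	28
validated_assayed	48
prioritized_positive	41
prioritized_assayed	66
cohort_carriers	12
cohort_size	718
frameshift_positive	24
frameshift_over_10pct	23
inframe_positive	17
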