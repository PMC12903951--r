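# Kit presets: adapter/primer pairs per library construction chemistry.
# front_ap: AP at the 5' end of a sense-oriented read.
# rear_ap: AP at the 3' end, given in sense orientation (its reverse
#   complement appears at the end of a plus-strand read as sequenced).
# These are configuration data taken from vendor/kit documentation; verify
# against the documentation for your kit version and edit as needed.
kit	front_ap	rear_ap
PCS109	TTTCTGTTGGTGCTGATATTGCTGGG	ACTTGCCTGTCGCTCTATCTTC
PCS111	TTTCTGTTGGTGCTGATATTGCTGGG	ACTTGCCTGTCGCTCTATCTTC
PCS114	TTTCTGTTGGTGCTGATATTGCTGGG	ACTTGCCTGTCGCTCTATCTTC
LSK114	AATGTACTTCGTTCAGTTACGTATTGCT	AATGTACTTCGTTCAGTTACGTATTGCT
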