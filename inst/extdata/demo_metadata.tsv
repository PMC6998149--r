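sample_id	subject_id	role	arm	timepoint	donor_id
DON1_donor	DON1	donor	none	donor	NA
DON2_donor	DON2	donor	none	donor	NA
P01_W-2	P01	recipient	FMT	W-2	DON1
P01_D0	P01	recipient	FMT	D0	DON1
P01_W2	P01	recipient	FMT	W2	DON1
P01_W6	P01	recipient	FMT	W6	DON1
P02_W-2	P02	recipient	FMT	W-2	DON2
P02_D0	P02	recipient	FMT	D0	DON2
P02_W2	P02	recipient	FMT	W2	DON2
P02_W6	P02	recipient	FMT	W6	DON2
P03_W-2	P03	recipient	sham	W-2	NA
P03_D0	P03	recipient	sham	D0	NA
P03_W2	P03	recipient	sham	W2	NA
P03_W6	P03	recipient	sham	W6	NA
P04_W-2	P04	recipient	sham	W-2	NA
P04_D0	P04	recipient	sham	D0	NA
P04_W2	P04	recipient	sham	W2	NA
P04_W6	P04	recipient	sham	W6	NA
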