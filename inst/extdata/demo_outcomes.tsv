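subject_id	arm	flare_week	flare_after	flare_by	dropout_week	dropout_in_remission
P01	FMT	NA	NA	NA	NA	FALSE
P02	FMT	NA	NA	NA	NA	FALSE
P03	sham	18	17	18	NA	FALSE
P04	sham	NA	NA	NA	NA	FALSE
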