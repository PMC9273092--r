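quantity	numerator	denominator	printed_pct
admissions_any_subcategory	19380	23904	81
notes_any_subcategory	209697	418393	50
admissions_reduced_signal	18192	23904	76
admissions_possibility	7134	23904	29.8
expired_followup_full	10772	23904	45
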