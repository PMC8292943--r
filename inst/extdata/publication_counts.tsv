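# Published corpus tallies: per-region totals of health-informatics (H-I
# co-indexed) publications and of the AI and EHR topical subsets. The
# global denominator is the full included corpus.
region	hi_publications	ai_publications	ehr_publications
Global	194567	13258	NA
China	14105	1592	193
United States	49353	3628	NA
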