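column	description
gene_region	Region (amplicon/locus) name; the totals row is named TOTAL
n_cpgs_per_region	Number of CpG dinucleotides in the amplicon reference
n_cells_analyzed	Distinct cells retained for this region after conversion QC
total_cpgs	Evaluable cell-by-CpG observations (AMBIGUOUS calls and MIXED-bulk CpGs excluded)
n_demethylating	Cell-by-CpG observations unmethylated or hemi-methylated at a bulk-methylated CpG
n_methylating	Cell-by-CpG observations methylated or hemi-methylated at a bulk-unmethylated CpG
non_cpg_converted	Non-CpG cytosine positions read as T (converted) across retained cells
non_cpg_total	Evaluable non-CpG cytosine positions (T, C or Y) across retained cells
demethylating_rate_pct	100 * n_demethylating / total_cpgs, unrounded (totals row only)
methylating_rate_pct	100 * n_methylating / total_cpgs, unrounded (totals row only)
conversion_rate_pct	100 * non_cpg_converted / non_cpg_total, unrounded (totals row only)
demethylating_rate_label	Demethylating rate rounded half-away-from-zero to one decimal (totals row only)
methylating_rate_label	Methylating rate rounded half-away-from-zero to one decimal (totals row only)
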