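quantity	value
induced_genes	368
repressed_genes	245
responsive_genes	613
bound_induced_genes	61
bound_genes	158
bound_responsive_genes	71
major_common_sites	146
tandem_sites	85
divergent_sites	61
divergent_shared_sites	12
sensitive_bound_strains	6
assayed_bound_strains	26
sensitive_unbound_strains	1
assayed_unbound_strains	34
sty1_dependent_genes	31
sty1_recruited_genes	101
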