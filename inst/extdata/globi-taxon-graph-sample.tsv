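providedTaxonId	providedTaxonName	resolvedTaxonId	resolvedTaxonName
	Procladius sp1 M_PL_014	NCBI:1981571	Procladius
	Procladius sp1 M_PL_014	NCBI:1981569	Procladius
	Procladius sp1 M_PL_014	NCBI:1981572	Procladius
	Procladius sp1 M_PL_014	NCBI:1981573	Procladius
	Procladius sp1 M_PL_014	NCBI:1981574	Procladius
	Procladius sp1 M_PL_014	NCBI:1981570	Procladius
	Senecio pectinatus	GBIF:8317096	Senecio pectinatus
	Senecio pectinatus	GBIF:8414746	Senecio pectinatus
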