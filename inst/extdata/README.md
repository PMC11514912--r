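# extdata

Place the released 226-blastocyst feature table here as
`supplementary_table5.csv` (canonical schema `id, diameter_um, te_count,
te_density, te_size_variance, icm_area_um2, ploidy`, or use the
`column_mapping` argument of `read_feature_table()` for the original column
names) and reinstall the package. The cohort-reproduction tests in
`tests/testthat/test-acceptance.R` run against it; without the file they
fail, everything else is fully synthetic.
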