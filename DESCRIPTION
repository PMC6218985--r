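Package: epidriver
Title: Pan-Cancer Detection of Driver Genes Associated with Genome-Wide
    Methylation and Expression Changes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Identifies cancer driver genes whose somatic mutations are
    associated with genome-wide DNA methylation changes (methylation driver
    genes, MDGs) or gene expression changes (expression driver genes, EDGs)
    across multiple tumor cohorts. Site-level mutant-versus-wild-type
    association is tested with Wilcoxon rank-sum tests on beta values (or
    Welch t-tests on expression), genome-wide differential counts serve as
    the per-cohort test statistic, significance is assessed against an
    empirical null pool built from passenger-gene mutations, per-cohort
    counts are aggregated into pan-cancer resampling p-values, and multiple
    testing is controlled with a grouped Benjamini-Hochberg adjustment.
    Downstream stages test chromatin-regulator enrichment among commonly
    dysregulated targets and the joint promoter-methylation by expression
    direction patterns of target genes. A synthetic multi-omics cohort
    generator with planted driver effects makes the whole pipeline testable
    without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    data.table,
    stats,
    utils
Suggests:
    jsonlite,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
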