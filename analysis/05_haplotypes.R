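#!/usr/bin/env Rscript
# Stage 5: haplotype enumeration, Duncan grouping, superior-haplotype call.
#
# Enumerates gene haplotypes from the SNP matrix (heterozygous or missing
# carriers excluded), associates them with 100-seed weight via Duncan's
# multiple range test, and calls the superior haplotype when the best and
# worst groups fall in disjoint letter groups.

suppressPackageStartupMessages(library(panhap))

seed <- 20260920L
out <- "results"
dir.create(out, showWarnings = FALSE, recursive = TRUE)

calls_df <- read.csv("results/simulated/genotypes.csv", check.names = FALSE,
                     stringsAsFactors = FALSE)
calls <- as.matrix(calls_df[, -1L])
rownames(calls) <- calls_df$accession
sites <- read.csv("results/simulated/snp_sites.csv", stringsAsFactors = FALSE)
genotypes <- snp_matrix(calls, sites)
phenotypes <- read_phenotypes("results/simulated/phenotypes.csv")

ht <- enumerate_haplotypes(genotypes)
print(ht)
message(nrow(ht$excluded), " accessions excluded (",
        sum(ht$excluded$reason == "het"), " het, ",
        sum(ht$excluded$reason == "missing"), " missing)")

call <- call_superior_haplotype(ht, phenotypes, min_n = 5L)
print(call$grouping)
message("superior haplotype: ", call$superior,
        " | inferior haplotype: ", call$inferior)

write.csv(call$grouping$groups, file.path(out, "duncan_grouping.csv"),
          row.names = FALSE)
write.csv(data.frame(accession = names(ht$assignment),
                     haplotype = unname(ht$assignment)),
          file.path(out, "haplotype_assignments.csv"), row.names = FALSE)
write.csv(data.frame(superior = call$superior, inferior = call$inferior,
                     min_n = call$min_n),
          file.path(out, "superior_call.csv"), row.names = FALSE)

write_run_manifest(file.path(out, "MANIFEST_haplotypes.txt"),
                   list(stage = "haplotypes", seed = seed,
                        superior = call$superior, inferior = call$inferior))
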