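#!/usr/bin/env Rscript
# Stage 6: KASP marker scoring across cultivars.
#
# Builds a synthetic 23-marker x 16-cultivar panel mirroring the study's
# validation design (a donor genotype carrying the superior alleles, 20
# of 23 markers polymorphic against it) and scores polymorphism and
# superior-allele presence.

suppressPackageStartupMessages(library(panhap))

seed <- 20260920L
out <- "results"
dir.create(out, showWarnings = FALSE, recursive = TRUE)

set.seed(derive_seed(seed, "kasp"))
cultivars <- c("ICC4958", sprintf("cv%02d", 1:15))
calls <- matrix("A", 23L, 16L,
                dimnames = list(sprintf("CKAM%04d", 2200 + 1:23), cultivars))
poly <- sample(23L, 20L)
for (m in poly) calls[m, 1L + sample(15L, sample(1:15, 1L))] <- "B"
km <- kasp_matrix(calls, superior_allele = rep("A", 23L), donor = "ICC4958")

sc <- score_markers(km)
message(sum(sc$markers$polymorphic), " of ", nrow(sc$markers),
        " markers polymorphic between the donor and the cultivars")
carriers <- colSums(sc$presence)
message("cultivars carrying the superior allele at all markers: ",
        sum(carriers == nrow(calls)))

write.csv(sc$markers, file.path(out, "kasp_markers.csv"), row.names = FALSE)
write.csv(cbind(marker = rownames(sc$presence), as.data.frame(sc$presence)),
          file.path(out, "kasp_presence.csv"), row.names = FALSE)

write_run_manifest(file.path(out, "MANIFEST_kasp.txt"),
                   list(stage = "kasp", seed = seed,
                        polymorphic = sum(sc$markers$polymorphic)))
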