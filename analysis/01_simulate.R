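#!/usr/bin/env Rscript
# Stage 1: generate every synthetic input for the downstream analyses.
#
# The pan-genome matrix reproduces the composition of a 17-genome
# cultivated-chickpea pan-genome (34,345 gene families split
# 17,483 / 2,656 / 13,986 / 220 across core / softcore / dispensable /
# private).  The annotated toy genome, variant set, SV call sets and
# haplotype-phenotype dataset all carry planted ground truth.

suppressPackageStartupMessages(library(panhap))

seed <- 20260920L
out <- "results/simulated"
dir.create(out, showWarnings = FALSE, recursive = TRUE)

pg <- generate_pangenome_matrix(pangenome_sim_spec(seed = seed))
og <- pa_matrix_to_orthogroups(pg$matrix)
write_orthogroups(og, file.path(out, "orthogroups.tsv"))
write.csv(data.frame(family_id = names(pg$truth), class = pg$truth),
          file.path(out, "pangenome_truth.csv"), row.names = FALSE)
message("pan-genome matrix: ", nrow(pg$matrix$occupancy), " families x ",
        ncol(pg$matrix$occupancy), " genomes")

sim <- generate_annotated_genome(n_chroms = 3L, n_genes = 24L, seed = seed)
write_genome_fasta(sim$genome, file.path(out, "genome.fa"))
write_gff3(sim$genes, file.path(out, "genes.gff3"))

vv <- generate_variants(
  sim$genome, sim$genes,
  c(intergenic = 120L, intronic = 90L, utr = 60L, synonymous = 70L,
    missense = 70L, nonsense = 25L, splice_donor = 20L,
    splice_acceptor = 20L, frameshift = 15L, inframe = 10L),
  seed = seed)
write_vcf(vv$variants, file.path(out, "variants.vcf"))
write.csv(vv$truth, file.path(out, "variant_truth.csv"), row.names = FALSE)
message("variants: ", nrow(vv$variants$records), " planted across ",
        length(unique(vv$truth$class)), " effect classes")

sv <- generate_sv_callsets(n_samples = 6L, n_clusters = 40L, jitter_sd = 60,
                           seed = seed)
write.csv(sv$records, file.path(out, "sv_records.csv"), row.names = FALSE)
write.csv(sv$truth, file.path(out, "sv_truth.csv"), row.names = FALSE)

hap <- generate_haplotype_dataset(haplotype_sim_spec(seed = seed))
write.csv(hap$phenotypes, file.path(out, "phenotypes.csv"), row.names = FALSE)
write.csv(cbind(accession = rownames(hap$genotypes$calls),
                as.data.frame(hap$genotypes$calls)),
          file.path(out, "genotypes.csv"), row.names = FALSE)
write.csv(hap$genotypes$sites, file.path(out, "snp_sites.csv"),
          row.names = FALSE)

write_run_manifest(file.path(out, "MANIFEST.txt"),
                   list(stage = "simulate", seed = seed,
                        n_genomes = 17, n_families = 34345,
                        n_variants = nrow(vv$variants$records),
                        n_sv_clusters = 40, n_accessions = 200))
message("stage 1 outputs in ", out)
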