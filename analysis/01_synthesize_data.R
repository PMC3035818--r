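#!/usr/bin/env Rscript
# Stage 1: generate the study-shaped synthetic data set.
#
# 125 recipient-species and 15 donor-species individuals typed at 25
# microsatellites (one 4th-chromosome locus fixed in both species, five
# loci introgressed, i.e. simulated with both samples drawn from one
# pool), plus an mtDNA alignment with a 737-site silent mask in which
# the introgressed maIII-like class sits 3 silent substitutions from its
# nearest donor haplotype.

suppressPackageStartupMessages(library(introscan))

seed <- 20260929L
set.seed(seed)
spec <- synth_spec()
paths <- write_synthetic_dataset(spec, "results/data")

cat("wrote:\n")
print(paths)
cat("introgressed microsatellite loci:",
    paste(attr(paths, "introgressed_loci"), collapse = ", "), "\n")
cat("haplogroup plan:\n")
print(spec$haplogroup_plan)
writeLines(attr(paths, "introgressed_loci"),
           "results/data/introgressed_loci.txt")
writeLines(as.character(seed), "results/data/seed.txt")
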