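#!/usr/bin/env Rscript
# OPTIONAL, network-dependent validation against public resources.  Not run
# by the test suite: it downloads the pinned PhyloTree 17 Forensic Update 1.2
# haplogroup list to recompute the name-irregularity statistics (6380
# haplogroups; ~1.8% with consecutive uppercase letters, ~2.8% with
# consecutive lowercase letters, ~19% with modifier symbols), and sketches
# the 1KGP African-ancestry pipeline (SC = 9 groups, SCL = 14 groups,
# max-clade at 0.003 = 29 groups).  The 1KGP leg additionally requires
# haplogroup calling and maximum-likelihood tree inference outside this
# package, so it is documented here as a recipe rather than executed.
#
# Usage: Rscript scripts/external_validation.R --phylotree <haplogroups.txt>
# where the file is the one-name-per-line haplogroup list exported from
# https://haplogrep.i-med.ac.at/phylogenies/phylotree-fu-rcrs@1.2

suppressPackageStartupMessages(library(mtgrouper))

args <- commandArgs(trailingOnly = TRUE)
if (length(args) < 2 || args[1] != "--phylotree") {
  message("usage: Rscript scripts/external_validation.R --phylotree FILE")
  message("FILE: haplogroup names of phylotree-fu-rcrs@1.2, one per line")
  quit(save = "no", status = 2)
}
names_file <- args[2]

nm <- readLines(names_file, warn = FALSE)
nm <- nm[nzchar(trimws(nm))]
s <- classify_hg_names(nm)
print(s)
cat(sprintf("total haplogroups: %d (expected 6380 for the pinned build)\n",
            s$total))

message("\n1KGP recipe (not executed): retrieve the 660 unrelated African-",
        "ancestry mtDNA genomes (ACB, ASW, MSL, GWD, ESN, YRI, LWK), call ",
        "haplogroups, then:\n",
        "  length(unique(group_sc(calls)))   # 9 groups\n",
        "  length(unique(group_scl(calls)))  # 14 groups\n",
        "  max_clade_partition(tree, 0.003)$n_clusters  # 29 groups, tree-",
        "inference dependent")
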