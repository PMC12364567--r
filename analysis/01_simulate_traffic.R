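#!/usr/bin/env Rscript
# Simulate the mouse-scale systemic lipidomics inputs: 9 compartments
# (serum hub + 8 tissues), male and female phenotypes, n = 8 samples per
# (phenotype, compartment) cell, with planted A/U/B/N2 traffic and 10%
# detection dropout. Writes the abundance table, design, network and the
# planted truth under results/data/.

suppressMessages(library(lipidtraffic))

out <- file.path("results", "data")
dir.create(out, showWarnings = FALSE, recursive = TRUE)
seed <- 20L

net <- default_compartment_network()
truth <- plant_traffic_truth(net, c(A = 15, U = 15, B = 15, N2 = 15,
                                    PARTIAL = 10),
                             phenotypes = c("F", "M"),
                             class_pool = c("PC", "TG"), seed = seed)
# introduce a phenotype contrast: a third of the U-type variables are
# confined to vastus muscle in males only (absent in females)
u_vars <- unique(truth$variable[truth$planted_label == "U"])
flip <- u_vars[seq_len(5)]
truth$planted_compartments[truth$variable %in% flip &
                             truth$phenotype == "M"] <- "vastus muscle"
truth$planted_compartments[truth$variable %in% flip &
                             truth$phenotype == "F"] <- ""

sim <- generate_traffic_dataset(traffic_sim_spec(net, truth, n_per_group = 8,
                                                 dropout = 0.10, seed = seed))

write_abundance_table(sim$table, file.path(out, "abundance.csv"))
utils::write.csv(sim$design, file.path(out, "design.csv"), row.names = FALSE)
write_network(net, file.path(out, "network.json"))
utils::write.csv(sim$truth, file.path(out, "planted_truth.csv"),
                 row.names = FALSE)

cat("Simulated", length(sim$table$samples), "samples x",
    nrow(sim$table$variables), "lipid variables across",
    length(net$nodes), "compartments (seed", seed, ")\n")
cat("Planted:", paste(capture.output(print(table(
  truth$planted_label[truth$phenotype == "F"]))), collapse = "\n"), "\n")
cat("Files written under", out, "\n")
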