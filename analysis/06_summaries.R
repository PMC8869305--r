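#!/usr/bin/env Rscript
# Collects the shear and torque tables into comparison figures: average
# mid-substance von Mises stress versus load per ligament and damage
# scenario. Requires 04 and 05 to have run.
library(kneedamage)
stopifnot(file.exists("results/shear_summary.csv"))

plot_mode <- function(file, out, xlab) {
  tab <- read.csv(file)
  tab <- tab[tab$ligament != "ACL", ]
  pdf(out, width = 9, height = 3.2)
  op <- par(mfrow = c(1, 3), mar = c(4, 4, 2, 1))
  for (lig in unique(tab$ligament)) {
    d <- tab[tab$ligament == lig, ]
    plot(range(d$load), range(d$avg_vm_Pa) / 1e6, type = "n",
         xlab = xlab, ylab = "avg mid-substance vM (MPa)", main = lig)
    for (i in seq_along(unique(d$scenario))) {
      scen <- unique(d$scenario)[i]
      dd <- d[d$scenario == scen, ]
      lines(dd$load, dd$avg_vm_Pa / 1e6, col = i, lwd = 2)
    }
    legend("topleft", legend = unique(d$scenario), col = seq_along(unique(d$scenario)),
           lwd = 2, bty = "n", cex = 0.8)
  }
  par(op); dev.off()
}
plot_mode("results/shear_summary.csv", "results/shear_comparison.pdf",
          "anterior shear (N)")
if (file.exists("results/torque_summary.csv"))
  plot_mode("results/torque_summary.csv", "results/torque_comparison.pdf",
            "internal tibial torque (N m)")
cat("figures written under results/\n")
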