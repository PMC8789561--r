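#!/usr/bin/env Rscript
# Stage 5: SDG progress classification and summary tables.
#
# Classifies every country against the SDG targets (U5MR 25, NMR 12) from
# its 2019 estimate and 2010-19 ARR, bands the countries needing
# acceleration by how many-fold their pace must rise, and builds the
# regional summary table (rates, declines, death shares) from the earlier
# stages' outputs.

library(childmort)

fit <- readRDS("scratch/fit.rds")
groups <- read.csv("results/world/groups.csv")
u5 <- read_estimates("results/u5mr_estimates.csv")
nm <- read_estimates("results/nmr_estimates.csv")
deaths_reg <- read.csv("results/deaths_by_region.csv")

rate_at <- function(est, y) {
  at <- est[floor(est$year) == y, ]
  setNames(at$median, at$country)
}
arr_of <- function(est) {
  r10 <- rate_at(est, 2010); r19 <- rate_at(est, 2019)
  compute_arr(r10, r19[names(r10)], 2010, 2019)
}

for (ind in c("U5MR", "NMR")) {
  est <- if (ind == "U5MR") u5 else nm
  target <- if (ind == "U5MR") 25 else 12
  p <- classify_progress(rate_at(est, 2019), arr_of(est), target,
                         country = names(rate_at(est, 2019)))
  write.csv(p, sprintf("results/progress_%s.csv", tolower(ind)),
            row.names = FALSE)
  n_band <- table(factor(p$band[p$status == "acceleration_needed"],
                         c("<2", ">=2", ">=3")))
  cat(sprintf("%s target %g: %d achieved, %d on track, %d need acceleration\n",
              ind, target, sum(p$status == "achieved"),
              sum(p$status == "on_track"),
              sum(p$status == "acceleration_needed")))
  cat(sprintf("  of those, %d must at least triple and %d at least double their pace;\n",
              n_band[[">=3"]], n_band[[">=2"]]))
  cat(sprintf("  %d would not reach the target until after 2099\n",
              sum(p$achievement_label == ">2099")))
}

# regional summary in the style of the published global/regional tables
world_rate <- function(est, groups, y) {
  # births-weighted regional rates from the posterior medians
  at <- est[floor(est$year) == y, ]
  merge(at, groups, by = "country")
}
lb <- read_livebirths("results/world/livebirths.csv")
rows <- list()
for (g in c("World", sort(unique(groups$region)))) {
  members <- if (g == "World") groups$country
             else groups$country[groups$region == g]
  b19 <- lb$births[lb$year == 2019][match(members,
                                          lb$country[lb$year == 2019])]
  r <- function(est, y) {
    at <- est[floor(est$year) == y & est$country %in% members, ]
    sum(at$median * b19[match(at$country, members)]) / sum(b19)
  }
  dg <- deaths_reg[deaths_reg$group == (if (g == "World") "World" else g), ]
  d19 <- dg$deaths_under5[dg$year == 2019]
  d90 <- dg$deaths_under5[dg$year == 1990]
  dw <- deaths_reg[deaths_reg$group == "World", ]
  rows[[g]] <- data.frame(
    group = g,
    u5mr_1990 = report_round(r(u5, 1990)), u5mr_2019 = report_round(r(u5, 2019)),
    u5mr_decline_pct = percent_decline(r(u5, 1990), r(u5, 2019)),
    nmr_1990 = report_round(r(nm, 1990)), nmr_2019 = report_round(r(nm, 2019)),
    deaths_1990 = round(d90), deaths_2019 = round(d19),
    deaths_decline_pct = percent_decline(d90, d19),
    share_2019_pct = percent_share(d19,
                                   dw$deaths_under5[dw$year == 2019]))
}
tab <- do.call(rbind, rows)
write.csv(tab, "results/regional_summary.csv", row.names = FALSE)
cat("\nRegional summary (synthetic world):\n")
print(tab, row.names = FALSE)
cat("Wrote results/progress_{u5mr,nmr}.csv, results/regional_summary.csv\n")
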