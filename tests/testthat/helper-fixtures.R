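# shared fixture builders (oracles live in the test files themselves)

# long abundance tibble from a feature x sample matrix
toy_abundance <- function(m, sites = NULL) {
  tbl <- tibble::as_tibble(m, rownames = "feature") |>
    tidyr::pivot_longer(-feature, names_to = "sample",
                        values_to = "abundance")
  if (!is.null(sites)) tbl$site <- unname(sites[tbl$sample])
  tbl
}

# a gridded day (480 points at 3-min spacing) for a given value function
grid_day <- function(value_fn, variable = "RH", date = as.Date("2018-02-01"),
                     site = "s", position = "top", replicate = "r1") {
  minute <- seq(0, 1437, by = 3)
  tibble::tibble(
    site = site, position = position, replicate = replicate,
    date = date, variable = variable,
    minute = minute, value = value_fn(minute)
  )
}

# habitability-day tibble over consecutive dates
hab_days_fixture <- function(wet_hours,
                             start = as.Date("2018-02-01")) {
  tibble::tibble(
    date = start + seq_along(wet_hours) - 1,
    wet_hours = wet_hours,
    wetlight_hours = 0
  )
}

random_aa_sequence <- function(len) {
  paste(sample(c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L", "M",
                 "N", "P", "Q", "R", "S", "T", "V", "W", "Y"),
               len, replace = TRUE), collapse = "")
}

# independent fine-grid pH-scan oracle for the isoelectric point:
# locate the sign change of the net charge on a coarse grid, then refine
# at 1e-4 resolution inside the bracket
scan_pi_oracle <- function(sequence, pka = halohab::pka_set()) {
  coarse <- seq(0, 14, by = 0.01)
  ch <- halohab::net_charge(sequence, coarse, pka)
  i <- max(which(ch > 0))
  fine <- seq(coarse[i], coarse[min(i + 1, length(coarse))], by = 1e-4)
  chf <- halohab::net_charge(sequence, fine, pka)
  j <- max(which(chf > 0))
  (fine[j] + fine[min(j + 1, length(fine))]) / 2
}
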