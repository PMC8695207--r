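# shared helpers: a descriptor set at the published reference point, and a
# writer for small throwaway CSV libraries

at_reference <- function(...) {
  base <- list(molar_mass = 317, aromatic_pct = 25, psa = 72, logd74 = 2.2,
               logs = -3.5, logp = 2.9, rotatable_bonds = 5L, hba74 = 2L,
               hbd74 = 0L, formal_charge74 = 0L)
  utils::modifyList(base, list(...))
}

write_temp_library <- function(records, ext = ".csv") {
  path <- tempfile(fileext = ext)
  utils::write.csv(records, path, row.names = FALSE, quote = FALSE)
  path
}

# frozen printed scoring constants, typed from the published tables and kept
# independent of default_rules() so tests compare two routes
published_band_table <- function() {
  rbind(molar_mass = c(1.5, 1.0, 0.5, -1.0),
        aromatic_pct = c(1.5, 1.0, 0.5, -1.0),
        psa = c(1.5, 1.0, 0.5, -1.0),
        logd74 = c(1.5, 1.0, 0.5, -1.0),
        logs = c(1.5, 1.0, 0.5, -1.0),
        logp = c(3.0, 2.0, 1.0, -1.0))
}

published_offset_table <- function(hba_na = c(0.5, 1.0)) {
  rbind(rotatable_bonds = c(0.5, 1.0, 1.5, 1.0, 0.5, -1.0),
        hba74 = c(hba_na, 1.5, 1.0, 0.5, -1.0),
        hbd74 = c(0.5, 1.0, 1.5, 1.0, 0.5, -1.0),
        formal_charge74 = c(1.0, 2.0, 3.0, 2.0, -3.0, -1.0))
}

published_means <- function() {
  data.frame(mean = c(317, 25, 72, 2.2, -3.5, 2.9),
             sd = c(88, 12, 39, 2.4, 1, 1.5),
             row.names = c("molar_mass", "aromatic_pct", "psa",
                           "logd74", "logs", "logp"))
}
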