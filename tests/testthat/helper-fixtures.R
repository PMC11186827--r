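# Shared fixtures: paths, frozen expected case tables, and small
# profile builders used across the test files.

fixture <- function(name) {
  path <- system.file("extdata", name, package = "hazrank")
  if (!nzchar(path)) stop("missing fixture: ", name)
  path
}

lv <- function(x) hazard_level(x)

# expected end-to-end levels for the manure case study (published
# prioritisation table; persistence collapsed over manure and soil)
case1_expected <- data.frame(
  hazard_id = c("(fluoro)quinolones", "macrolides", "sulphonamides",
                "tetracyclines", "E. coli", "Salmonella spp."),
  occurrence = c("H", "L", "L", "H", "H", "L"),
  persistence = c("H", "M", "L", "M", "L", "L"),
  transfer_accumulation = c("L", "L", "H", "L", "M", "M"),
  severity = c("H", "M", "L", "M", "M", "M"),
  presence = c("H", "L", "L", "M", "M", "L"),
  priority = c("H", "L", "L", "M", "M", "L"),
  stringsAsFactors = FALSE
)

# published pathogen severity table: DALY/case -> class
daly_table <- data.frame(
  pathogen = c("Bacillus cereus", "Clostridium perfringens",
               "Cryptosporidium spp", "Giardia spp", "norovirus",
               "Rotavirus", "Staphylococcus aureus", "Campylobacter",
               "Hepatitis A virus", "Hepatitis E virus", "STEC O157",
               "Salmonella spp", "Listeria monocytogenes",
               "Toxoplasma gondii"),
  daly = c(0.0023, 0.0032, 0.0024, 0.0018, 0.0026, 0.0054, 0.0026,
           0.034, 0.161, 0.434, 0.065, 0.039, 1.161, 3.173),
  class = c("L", "L", "L", "L", "L", "L", "L", "M", "H", "H", "M", "M",
            "H", "H"),
  stringsAsFactors = FALSE
)

# a minimal valid environment-route profile built in code
make_env_profile <- function(id = "toy", occ = 100, dt50 = 10,
                             log_koc = 3, hbgv = 50) {
  df <- data.frame(
    hazard_id = id, hazard_class = "chemical", route = "environment",
    evidence_kind = c("occurrence_concentration", "dt50", "log_koc",
                      "hbgv"),
    compartment = c("manure", "manure", "", ""),
    value = as.character(c(occ, dt50, log_koc, hbgv)),
    units = c("ng/g dm", "days", "", "ug/kg bw"),
    basis = c("", "", "", "per_day"),
    stringsAsFactors = FALSE
  )
  path <- tempfile(fileext = ".csv")
  utils::write.csv(df, path, row.names = FALSE)
  load_hazard_registry(path)[[1L]]
}

# exact mixed-chain exceedance for n fields via enumeration over all
# ordered n-tuples of pool values: the independent oracle for the
# Monte-Carlo engine
enumerate_exceedance <- function(values, n, limit) {
  grids <- expand.grid(rep(list(values), n))
  mean(rowMeans(grids) > limit)
}
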