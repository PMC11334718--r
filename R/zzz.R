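#' @keywords internal
#' @import data.table
"_PACKAGE"

.datatable.aware <- TRUE

# silence R CMD check notes for data.table NSE columns
utils::globalVariables(c(
  "element", "tag", "frame", "id", "time", "x", "y", "z", "mol",
  "z_above", "zw", "nwat", "i.event", "x.nwat", "site", "state",
  "species", "rshell", "px", "py", "pz", "ptag", "n_total", "zbin",
  "water_O", "count", "ix", "iy", "iz", "N", "f0", "f1", "hx", "hy",
  "hz", "n_water", "p"
))
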