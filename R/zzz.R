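#' @importFrom data.table := .N .I .SD .BY data.table as.data.table setorder
#'   setorderv setnames shift copy rbindlist
NULL

.datatable.aware <- TRUE

utils::globalVariables(c(
  ".", "..cols", "..key", ".fid", "bubble", "bubble_id", "category", "ci",
  "cj", "d", "di", "dist_deg", "dj", "fix_index", "frac", "kind", "n_fix",
  "next_bubble", "next_dist", "next_kind", "participant", "prev_bubble",
  "response", "stimulus", "subsequent", "task", "tot", "trial_id",
  "x_deg", "y_deg", "x_deg.x", "x_deg.y", "y_deg.x", "y_deg.y"
))
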