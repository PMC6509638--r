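#' @keywords internal
"_PACKAGE"

## Condition helpers -------------------------------------------------------

# All package errors carry class c(<specific>, "nv_error", "error",
# "condition") so callers (and the CLI) can trap them as a family.
nv_abort <- function(msg, class, ...) {
  stop(structure(
    class = c(class, "nv_error", "error", "condition"),
    list(message = msg, call = sys.call(-1), ...)
  ))
}

nv_warn <- function(msg, class = "nv_warning") {
  warning(structure(
    class = c(class, "nv_warning", "warning", "condition"),
    list(message = msg, call = sys.call(-1))
  ))
}

# strip surrounding whitespace only; internal spaces are part of the id
trim_ws <- function(x) sub("^[ \t\r]+", "", sub("[ \t\r]+$", "", x))

is_string <- function(x) is.character(x) && length(x) == 1L && !is.na(x)

`%||%` <- function(a, b) if (is.null(a)) b else a

## Shared vocabulary -------------------------------------------------------

ANNOTATION_CATEGORIES <- c("PATHWAY", "GO_BP", "GO_MF", "GO_CC")
DIRECTION_LEVELS <- c("UP", "DOWN", "DISCORDANT")

# Okabe-Ito colorblind-safe palette, 8 entries, assigned to experiments by
# input order.
EXPERIMENT_PALETTE <- c(
  "#E69F00", "#56B4E9", "#009E73", "#F0E442",
  "#0072B2", "#D55E00", "#CC79A7", "#999999"
)

# gene node fill by cross-experiment regulation class
GENE_COLORS <- c(UP = "#E41A1C", DOWN = "#377EB8", DISCORDANT = "#FFD92F")

# edge stroke by direction code (1 = up, 2 = down)
EDGE_COLORS <- c(`1` = "#E41A1C", `2` = "#377EB8")

# default layout seed used whenever the caller does not supply one
DEFAULT_SEED <- 42L
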