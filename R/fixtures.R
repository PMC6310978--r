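# Packaged pilot fixtures: the Indonesian off-patent procurement framework
# (8 + 1 draft criteria, 6 + 1 after the workshop's majority-vote exclusions),
# the workshop vote records, and four hypothetical tender test cases.
#
# Category score fractions are the package default: equally spaced across the
# non-exclusion categories of each criterion (worst = 0, best = 1); every
# fraction is overridable in the YAML config.

indonesia_criteria_spec <- function() {
  list(
    list(id = "equivalence",
         name = "Equivalence with the reference (original) product",
         definition = paste("Evidence on health outcomes from pharmaceutical-,",
                            "bioequivalence- and clinical trials"),
         labels = c("no-pe-data", "pe", "interchangeability-local", "be-local",
                    "be-ema-fda", "therapeutic-equivalence",
                    "improved-efficacy-safety"),
         descriptions = c(
           "No data on pharmaceutical equivalence",
           "Pharmaceutical equivalence",
           "Interchangeability defined based on local criteria",
           "Bioequivalence proven based on local criteria",
           "Bioequivalence proven based on European EMA or US FDA criteria",
           "Therapeutic equivalence proven in clinical trial",
           "Improvement in efficacy and/or safety based on clinical trial data")),
    list(id = "real-world-outcomes",
         name = "Real world clinical or economic outcomes",
         definition = paste("Evidence on effectiveness and costs (adherence,",
                            "tolerability, non-drug costs) from real-world data"),
         labels = c("no-rwd", "intl-rwd-equal", "local-rwd-equal",
                    "intl-rwd-improved", "local-rwd-improved"),
         descriptions = c(
           "No real world data on equal tolerability, adherence or non-drug cost",
           "International real world data on equal outcomes",
           "Local real world data on equal outcomes",
           "International real world data on improved outcomes",
           "Local real world data on improved outcomes")),
    list(id = "stability-formulation",
         name = "Product stability and drug formulation",
         definition = "Evidence on stability and drug formulation",
         labels = c("no-stability-data", "non-inferior-local", "improved-expiry",
                    "improved-stability-local", "improved-expiry-and-stability"),
         descriptions = c(
           "No data on product expiry or stability",
           "Data on non-inferior product expiry or stability in local environment",
           "Data on improved product expiry",
           "Data on improved product stability in local environment",
           "Data on improved product expiry and stability in local environment")),
    list(id = "quality-assurance",
         name = "Quality assurance",
         definition = paste("Evidence on manufacturing- and product quality",
                            "and standardisation"),
         labels = c("limited-info", "non-gmp-api", "non-gmp-full", "who-gmp",
                    "eu-pics-gmp"),
         descriptions = c(
           "Limited information on quality assurance",
           "Local/non GMP quality assurance only for active product ingredient",
           "Local/non GMP quality assurance for the entire manufacturing process",
           "WHO GMP certification",
           "EU or PIC/S GMP")),
    list(id = "macroeconomic-benefit",
         name = "Macroeconomic benefit",
         definition = paste("Wider economic benefits of selecting the medicine",
                            "(tax, investment, employment)"),
         labels = c("no-local-investment", "minor-local-investment",
                    "moderate-local-investment", "significant-local-investment"),
         descriptions = c(
           "The manufacturer has no local investment in the country",
           "The manufacturer has minor local investment in the country",
           "The manufacturer has moderate local investment in the country",
           "The manufacturer has significant local investment in the country")),
    list(id = "supply-reliability",
         name = "Reliability of drug supply",
         definition = paste("Stability and reliability of drug supply",
                            "(history and future guarantee)"),
         labels = c("major-multiple-problems", "minor-frequent-problems",
                    "single-problem", "no-problems", "guaranteed-supply"),
         descriptions = c(
           "Major and multiple supply problems in the last 5 years",
           "Minor and fairly frequent supply problems in the last 5 years",
           "Single precedence of supply problems in the last 5 years",
           "No precedence of supply problems in the last 5 years",
           "Manufacturer is financially capable and willing to guarantee supply")),
    list(id = "pharmacovigilance",
         name = "Pharmacovigilance",
         definition = paste("Data collection and assessment on adverse events",
                            "of pharmaceuticals"),
         labels = c("no-pv-system", "qualified-person",
                    "qualified-person-and-system"),
         descriptions = c(
           "No pharmacovigilance system",
           "Qualified person for pharmacovigilance",
           "Qualified person and sophisticated system to collect data")),
    list(id = "added-value-services",
         name = "Added value service related to the product",
         definition = paste("Extra services provided alongside the drug with",
                            "quantifiable and demonstrated outcomes"),
         labels = c("no-service", "service-available",
                    "major-service-demonstrated"),
         descriptions = c(
           "No program or service",
           "Availability of value added service",
           "Major value added service with demonstrated outcomes")))
}

build_draft_framework <- function() {
  crits <- lapply(indonesia_criteria_spec(), function(sp) {
    criterion(id = sp$id, name = sp$name, definition = sp$definition,
              categories = category_scale(sp$labels,
                                          descriptions = sp$descriptions))
  })
  crits <- c(crits, list(criterion(
    id = "price", name = "Price",
    definition = paste("Acquisition cost of the pharmaceutical product",
                       "compared to the lowest price available"),
    is_price = TRUE)))
  mcda_framework(crits, name = "indonesia-opp-tender-draft", version = "1",
                 notes = "8 + 1 draft criteria before the pilot workshop")
}

fixture_path <- function(file) {
  p <- system.file("extdata", file, package = "tenderMCDA")
  if (!nzchar(p)) stop("packaged fixture not found: ", file, call. = FALSE)
  p
}

#' Packaged Indonesian pilot fixtures
#'
#' \code{opp_framework("draft")} returns the 8 + 1 criteria framework as it
#' stood before the pilot workshop (unweighted); \code{opp_framework("final")}
#' returns the 6 + 1 framework obtained by running the full elicitation
#' pipeline on the packaged vote records (price weight 40\%, cut-off +100\%,
#' final weights 18.8 / 12.5 / 12.5 / 8.4 / 4.2 / 3.6 percent after display
#' rounding). \code{opp_votes()} returns the workshop vote rounds and
#' \code{opp_test_cases()} the four hypothetical products (bids 2200, 2900,
#' 3000 and 3800 IDR) used to validate and fine-tune the framework.
#'
#' @param stage \code{"final"} (default) or \code{"draft"}.
#' @return \code{opp_framework}: an \code{mcda_framework}; \code{opp_votes}:
#'   a vote data.frame; \code{opp_test_cases}: a performance-matrix
#'   data.frame; \code{opp_fixtures}: list with all of them.
#' @export
opp_framework <- function(stage = c("final", "draft")) {
  stage <- match.arg(stage)
  draft <- read_framework(fixture_path("indonesia_draft.yaml"))
  if (stage == "draft") return(draft)
  fw <- elicit_framework(draft, opp_votes())
  fw$metadata$name <- "indonesia-opp-tender"
  fw$metadata$notes <- "6 + 1 criteria elicited in the pilot workshop"
  fw
}

#' @rdname opp_framework
#' @export
opp_votes <- function() read_votes(fixture_path("indonesia_votes.csv"))

#' @rdname opp_framework
#' @export
opp_test_cases <- function() {
  read_performance_matrix(fixture_path("indonesia_test_cases.csv"))
}

#' @rdname opp_framework
#' @export
opp_fixtures <- function() {
  list(draft = opp_framework("draft"), votes = opp_votes(),
       final = opp_framework("final"), test_cases = opp_test_cases())
}

#' Write all packaged fixtures to a directory
#'
#' Emits the draft and final framework configs, the vote CSV and the
#' test-case performance matrix in their documented formats.
#'
#' @param dir output directory (created if needed).
#' @return character vector of written paths, invisibly.
#' @export
emit_fixtures <- function(dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- c(
    write_framework(opp_framework("draft"),
                    file.path(dir, "indonesia_draft.yaml")),
    write_framework(opp_framework("final"),
                    file.path(dir, "indonesia_final.yaml")),
    write_votes(opp_votes(), file.path(dir, "indonesia_votes.csv")),
    {
      p <- file.path(dir, "indonesia_test_cases.csv")
      utils::write.csv(opp_test_cases(), p, row.names = FALSE, quote = FALSE)
      p
    })
  invisible(paths)
}
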