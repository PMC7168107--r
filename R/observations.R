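#' Build an observation set
#'
#' An observation records the outcome of a clinical test of one component:
#' `TRUE` means the test passed (motion/sensation not defected), `FALSE`
#' means it failed.  Under the weak fault model only failures carry
#' information.
#'
#' @param component character vector of component ids (at most one
#'   observation per component)
#' @param test_ok logical vector, parallel to `component`
#' @param model optional `anatomy_model`; when given, every observed
#'   component is checked to exist in the model
#' @return a named logical vector of class `observation_set`
#' @export
observation_set <- function(component = character(), test_ok = logical(),
                            model = NULL) {
  component <- as.character(component)
  test_ok <- as.logical(test_ok)
  if (length(component) != length(test_ok)) {
    physdx_error("physdx_validation_error",
                 "component and test_ok must have the same length")
  }
  if (anyNA(test_ok)) {
    physdx_error("physdx_validation_error", "test_ok must be TRUE or FALSE")
  }
  if (anyDuplicated(component)) {
    physdx_error("physdx_validation_error",
                 paste0("more than one observation for: ",
                        paste(unique(component[duplicated(component)]),
                              collapse = ", ")))
  }
  obs <- setNames(test_ok, component)
  if (!is.null(model)) am_check_id(model, component)
  structure(obs, class = "observation_set")
}

as_observation_set <- function(obs, model) {
  if (is.data.frame(obs)) {
    ok_col <- intersect(c("test_ok", "testOK"), names(obs))[1]
    obs <- observation_set(obs$component, obs[[ok_col]], model)
  } else if (is.logical(obs)) {
    obs <- observation_set(names(obs), unname(obs), model)
  } else {
    stopifnot(inherits(obs, "observation_set"))
    am_check_id(model, names(obs))
  }
  obs
}

#' Read observations from JSON
#'
#' Dialect: `[{"component": "...", "testOK": true|false}, ...]`.
#'
#' @param path path to an observation JSON file
#' @param model optional `anatomy_model` to validate against
#' @return an [observation_set()]
#' @export
load_observations <- function(path, model = NULL) {
  if (!file.exists(path)) {
    physdx_error("physdx_io_error", paste0("observation file not found: ", path))
  }
  parsed <- tryCatch(jsonlite::fromJSON(path, simplifyVector = TRUE),
                     error = function(e) {
                       physdx_error("physdx_parse_error",
                                    paste0("malformed observation file: ",
                                           conditionMessage(e)))
                     })
  if (length(parsed) == 0) return(observation_set())
  observation_set(parsed$component, parsed$testOK, model)
}

#' Write observations to JSON
#' @param obs an `observation_set`
#' @param path output file path
#' @return `path`, invisibly
#' @export
write_observations <- function(obs, path) {
  jsonlite::write_json(
    data.frame(component = names(obs), testOK = unname(unclass(obs))),
    path, auto_unbox = TRUE, pretty = TRUE)
  invisible(path)
}

#' @export
print.observation_set <- function(x, ...) {
  if (!length(x)) {
    cat("Empty observation set\n")
  } else {
    cat("Observations (", sum(!x), " failed / ", length(x), " total):\n", sep = "")
    cat(sprintf("  %s: %s\n", names(x), ifelse(x, "pass", "FAIL")), sep = "")
  }
  invisible(x)
}
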