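#' Construct a protocol specification
#'
#' The protocol is the planned intervention against which delivery and
#' receipt are measured: the intervention components, the per-participant
#' session plans with durations and pre-specified success criteria, and the
#' team-representation schedule used to score team-mode (participatory)
#' sessions.
#'
#' @param components data frame with columns `component_id`, `label`.
#' @param sessions data frame of session plans with columns `plan_id`,
#'   `component_id`, `duration_hours` (> 0), `receipt_mode`
#'   (`"individual"` or `"team"`), `has_intensity` (logical; `TRUE` only for
#'   physical-training sessions rated for group-level intensity), and a
#'   list-column `criteria` of success-criterion identifiers.
#' @param representation_schedule data frame with columns `min_size`,
#'   `max_size` (use `Inf` for the open top interval) and `required`, the
#'   number of team representatives required at a team-mode session. The
#'   intervals must tile all team sizes >= 1 with no gaps or overlaps.
#' @param total_hours planned intervention hours per participant; defaults
#'   to (and must equal) the sum of the plan durations.
#' @param name optional label for the protocol.
#' @return an object of class `protocol_spec`.
#' @seealso [read_protocol()], [default_protocol()]
#' @export
protocol_spec <- function(components, sessions, representation_schedule,
                          total_hours = NULL, name = "protocol") {
  components <- tibble::as_tibble(components)
  sessions <- tibble::as_tibble(sessions)
  representation_schedule <- tibble::as_tibble(representation_schedule)

  stopifnot(
    all(c("component_id", "label") %in% names(components)),
    all(c("plan_id", "component_id", "duration_hours", "receipt_mode",
          "has_intensity", "criteria") %in% names(sessions)),
    all(c("min_size", "max_size", "required") %in% names(representation_schedule))
  )
  if (anyDuplicated(components$component_id)) {
    stop("duplicate component ids in protocol", call. = FALSE)
  }
  if (anyDuplicated(sessions$plan_id)) {
    stop("duplicate session plan ids in protocol", call. = FALSE)
  }
  if (!all(sessions$component_id %in% components$component_id)) {
    bad <- setdiff(sessions$component_id, components$component_id)
    stop("session plan references undeclared component: ",
         paste(bad, collapse = ", "), call. = FALSE)
  }
  if (!all(sessions$duration_hours > 0)) {
    stop("all session durations must be > 0", call. = FALSE)
  }
  if (!all(sessions$receipt_mode %in% c("individual", "team"))) {
    stop("receipt_mode must be 'individual' or 'team'", call. = FALSE)
  }

  sched <- representation_schedule[order(representation_schedule$min_size), ]
  if (sched$min_size[1] > 1) {
    stop("representation schedule must cover team size 1", call. = FALSE)
  }
  if (nrow(sched) > 1) {
    gaps <- sched$min_size[-1] != sched$max_size[-nrow(sched)] + 1
    if (any(gaps)) {
      stop("representation schedule has gaps or overlaps between intervals",
           call. = FALSE)
    }
  }
  if (is.finite(sched$max_size[nrow(sched)])) {
    stop("representation schedule must be open-ended (max_size Inf) at the top",
         call. = FALSE)
  }
  if (!all(sched$required >= 1)) {
    stop("required representative counts must be >= 1", call. = FALSE)
  }

  planned_hours <- sum(sessions$duration_hours)
  if (is.null(total_hours)) total_hours <- planned_hours
  if (!isTRUE(all.equal(total_hours, planned_hours))) {
    stop(sprintf(
      "total_hours (%s) must equal the sum of planned session durations (%s)",
      format(total_hours), format(planned_hours)
    ), call. = FALSE)
  }

  structure(
    list(
      name = name,
      components = components,
      sessions = sessions,
      representation_schedule = sched,
      total_hours = total_hours
    ),
    class = "protocol_spec"
  )
}

#' @export
print.protocol_spec <- function(x, ...) {
  cat(sprintf(
    "<protocol_spec> %s: %d components, %d planned sessions, %g h per participant\n",
    x$name, nrow(x$components), nrow(x$sessions), x$total_hours
  ))
  per_comp <- stats::aggregate(
    duration_hours ~ component_id, data = x$sessions,
    FUN = function(d) c(n = length(d), h = sum(d))
  )
  for (i in seq_len(nrow(per_comp))) {
    cat(sprintf("  %s: %d sessions / %g h\n", per_comp$component_id[i],
                per_comp$duration_hours[i, "n"], per_comp$duration_hours[i, "h"]))
  }
  invisible(x)
}

#' Read or write a protocol specification as YAML
#'
#' The on-disk form mirrors [protocol_spec()]: top-level `name`,
#' `components` (id/label), `sessions` (id, component, duration_hours,
#' receipt_mode, has_intensity, criteria), and `representation_schedule`
#' (min_size, max_size — `.inf` for the open top — required).
#'
#' @param path file path of a YAML protocol document.
#' @return `read_protocol()` returns a `protocol_spec`; `write_protocol()`
#'   returns `path` invisibly.
#' @export
read_protocol <- function(path) {
  doc <- yaml::read_yaml(path)
  components <- tibble::tibble(
    component_id = vapply(doc$components, function(x) x$id, ""),
    label = vapply(doc$components, function(x) x$label %||% x$id, "")
  )
  sessions <- tibble::tibble(
    plan_id = vapply(doc$sessions, function(x) x$id, ""),
    component_id = vapply(doc$sessions, function(x) x$component, ""),
    duration_hours = vapply(doc$sessions, function(x) as.numeric(x$duration_hours), 0),
    receipt_mode = vapply(doc$sessions, function(x) x$receipt_mode %||% "individual", ""),
    has_intensity = vapply(doc$sessions, function(x) isTRUE(x$has_intensity), NA),
    criteria = lapply(doc$sessions, function(x) as.character(x$criteria))
  )
  sched <- tibble::tibble(
    min_size = vapply(doc$representation_schedule, function(x) as.numeric(x$min_size), 0),
    max_size = vapply(doc$representation_schedule, function(x) {
      m <- x$max_size
      if (is.null(m) || identical(m, ".inf")) Inf else as.numeric(m)
    }, 0),
    required = vapply(doc$representation_schedule, function(x) as.integer(x$required), 0L)
  )
  protocol_spec(components, sessions, sched,
                total_hours = doc$total_hours %||% NULL,
                name = doc$name %||% "protocol")
}

#' @rdname read_protocol
#' @param protocol a `protocol_spec`.
#' @export
write_protocol <- function(protocol, path) {
  stopifnot(inherits(protocol, "protocol_spec"))
  doc <- list(
    name = protocol$name,
    total_hours = protocol$total_hours,
    components = lapply(seq_len(nrow(protocol$components)), function(i) {
      list(id = protocol$components$component_id[i],
           label = protocol$components$label[i])
    }),
    sessions = lapply(seq_len(nrow(protocol$sessions)), function(i) {
      s <- protocol$sessions[i, ]
      list(id = s$plan_id, component = s$component_id,
           duration_hours = s$duration_hours, receipt_mode = s$receipt_mode,
           has_intensity = s$has_intensity, criteria = s$criteria[[1]])
    }),
    representation_schedule = lapply(seq_len(nrow(protocol$representation_schedule)), function(i) {
      r <- protocol$representation_schedule[i, ]
      list(min_size = r$min_size,
           max_size = if (is.finite(r$max_size)) r$max_size else ".inf",
           required = r$required)
    })
  )
  yaml::write_yaml(doc, path)
  invisible(path)
}

#' The packaged 19-session / 27-hour multi-component protocol
#'
#' Three components delivered over three months: participatory ergonomics
#' (a kick-off meeting plus four team-mode working-group/evaluation
#' sessions, 9 h), physical training (12 weekly 1-h group sessions rated
#' for intensity), and cognitive-behavioural training (two 3-h workshops).
#' 19 sessions, 27 planned hours per participant, 55 success criteria in
#' total, and the five-interval team-representation schedule
#' (<5 workers: 2 representatives; 5-9: 3; 10-14: 4; 15-19: 5; >=20: 6).
#'
#' @return a `protocol_spec`.
#' @export
default_protocol <- function() {
  read_protocol(system.file("extdata", "protocol_27h.yaml",
                            package = "impquant", mustWork = TRUE))
}
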