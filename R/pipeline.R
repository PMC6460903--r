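# Process/activity framework: a plugin registry of activity modules, an XML
# process-definition format (processList/process/moduleList/activity/
# inputList/outputList), fail-fast sequential execution with a progress
# monitor, and persistent parameter sets.

.hfo_registry <- new.env(parent = emptyenv())

node <- function(name, kind, value) list(name = name, kind = kind, value = value)

#' Register an activity module
#'
#' @param identifier Unique activity identifier (used as `module=` in
#'   process definitions).
#' @param factory Function `(inputs, params) -> node value`; `inputs` is a
#'   named list of resolved data nodes (roles: `primary`, `events`,
#'   `features`, `raw`), `params` a named list. Activities must not modify
#'   their inputs; they create new output nodes.
#' @param parameter_schema List of `list(name, default)` descriptors; the
#'   defaults fill unset parameters and drive validation.
#' @param kind Output node kind: `"recording"`, `"events"`, `"features"`
#'   or `"report"`.
#' @return The identifier, invisibly.
#' @export
register_activity <- function(identifier, factory, parameter_schema = list(),
                              kind = "events") {
  if (exists(identifier, envir = .hfo_registry, inherits = FALSE)) {
    stop("register_activity(): duplicate identifier '", identifier, "'")
  }
  assign(identifier,
         list(factory = factory, schema = parameter_schema, kind = kind),
         envir = .hfo_registry)
  invisible(identifier)
}

#' List / reset registered activities
#' @return `list_activities()` returns the sorted identifiers.
#' @export
list_activities <- function() sort(ls(.hfo_registry), method = "radix")

#' @rdname list_activities
#' @export
reset_registry <- function() {
  rm(list = ls(.hfo_registry), envir = .hfo_registry)
  register_builtin_activities()
  invisible(NULL)
}

schema_defaults <- function(schema) {
  out <- list()
  for (p in schema) out[[p$name]] <- p$default
  out
}

param_num <- function(params, name) {
  v <- params[[name]]
  if (is.character(v)) v <- as.numeric(v)
  v
}

register_builtin_activities <- function() {
  register_activity("fir_filter", kind = "recording",
    parameter_schema = list(list(name = "low_hz", default = 80),
                            list(name = "high_hz", default = 250),
                            list(name = "taps", default = 513),
                            list(name = "self_convolve", default = FALSE)),
    factory = function(inputs, params) {
      rec <- inputs$primary$value
      rate <- rec$epochs[[1L]][[1L]]$rate
      low <- param_num(params, "low_hz"); high <- param_num(params, "high_hz")
      k <- design_fir(if (!is.na(low) && low > 0) low,
                      if (!is.na(high) && high > 0) high,
                      rate = rate, taps = param_num(params, "taps"),
                      self_convolve = isTRUE(as.logical(params$self_convolve)))
      apply_fir(rec, k)
    })
  register_activity("emd_filter", kind = "recording",
    parameter_schema = list(list(name = "first_imf", default = 1),
                            list(name = "n_imfs", default = 1),
                            list(name = "epsilon", default = 0.2)),
    factory = function(inputs, params) {
      emd_highpass(inputs$primary$value, param_num(params, "first_imf"),
                   param_num(params, "n_imfs"), param_num(params, "epsilon"))
    })
  register_activity("rms_detector", kind = "events",
    parameter_schema = list(list(name = "window_s", default = 0.003),
                            list(name = "threshold_sd", default = 5),
                            list(name = "min_duration_s", default = 0.006),
                            list(name = "min_peaks", default = 6),
                            list(name = "peak_threshold_sd", default = 3),
                            list(name = "merge_gap_s", default = 0.010)),
    factory = function(inputs, params) {
      detect_rms(inputs$primary$value, rms_params(
        param_num(params, "window_s"), param_num(params, "threshold_sd"),
        param_num(params, "min_duration_s"), param_num(params, "min_peaks"),
        param_num(params, "peak_threshold_sd"), param_num(params, "merge_gap_s")))
    })
  register_activity("hilbert_detector", kind = "events",
    parameter_schema = list(list(name = "threshold_sd", default = 3),
                            list(name = "min_duration_s", default = 0.010),
                            list(name = "min_peaks", default = 6),
                            list(name = "peak_threshold_sd", default = 3),
                            list(name = "merge_gap_s", default = 0.010)),
    factory = function(inputs, params) {
      detect_hilbert(inputs$primary$value, hilbert_params(
        param_num(params, "threshold_sd"), param_num(params, "min_duration_s"),
        param_num(params, "min_peaks"), param_num(params, "peak_threshold_sd"),
        param_num(params, "merge_gap_s")))
    })
  register_activity("stockwell_classifier", kind = "events",
    parameter_schema = list(list(name = "f_min", default = 60),
                            list(name = "f_max", default = 500),
                            list(name = "ripple_boundary", default = 250),
                            list(name = "peak_trough_ratio", default = 2),
                            list(name = "context_s", default = 0.1)),
    factory = function(inputs, params) {
      classify_events_stockwell(
        inputs$events$value, inputs$primary$value,
        stockwell_params(param_num(params, "f_min"), param_num(params, "f_max"),
                         param_num(params, "ripple_boundary"),
                         param_num(params, "peak_trough_ratio"),
                         param_num(params, "context_s")))
    })
  register_activity("time_features", kind = "features",
    parameter_schema = list(list(name = "selection",
                                 default = paste(time_feature_names,
                                                 collapse = ",")),
                            list(name = "id", default = "time")),
    factory = function(inputs, params) {
      sel <- strsplit(params$selection, ",", fixed = TRUE)[[1L]]
      extract_time_features(inputs$events$value, inputs$primary$value,
                            trimws(sel), id = params$id)
    })
  register_activity("spectral_features", kind = "features",
    parameter_schema = list(list(name = "f_lo", default = 0),
                            list(name = "f_hi", default = 500),
                            list(name = "bin_hz", default = 10),
                            list(name = "normalize", default = TRUE),
                            list(name = "id", default = "spec")),
    factory = function(inputs, params) {
      extract_spectral_features(inputs$events$value, inputs$primary$value,
                                param_num(params, "f_lo"),
                                param_num(params, "f_hi"),
                                param_num(params, "bin_hz"),
                                isTRUE(as.logical(params$normalize)),
                                id = params$id)
    })
  register_activity("svm_classifier", kind = "events",
    parameter_schema = list(list(name = "model_file", default = "")),
    factory = function(inputs, params) {
      if (!nzchar(params$model_file)) {
        stop("svm_classifier: model_file parameter is required")
      }
      model <- load_model(params$model_file)
      tables <- inputs$features
      ft <- if (!is.null(tables$kind)) tables$value
            else concat_features(lapply(tables, `[[`, "value"))
      classify_events(model, ft)
    })
  # registry slot reserved: the bump-modeling classifier is not implemented
  # (the published description is insufficient); definitions referencing it
  # parse but fail at execution time.
  register_activity("bump_modeling", kind = "events",
    parameter_schema = list(),
    factory = function(inputs, params) {
      stop("bump_modeling classifier is not implemented")
    })
}

.onLoad <- function(libname, pkgname) {
  if (!length(ls(.hfo_registry))) register_builtin_activities()
}

#' Parse process definitions from XML
#'
#' The document layout mirrors the process-definition file format:
#' `processList` > `process` (attributes `name`, `reference`) >
#' `moduleList` > `activity` (attributes `activityName`, `module`) with
#' nested `inputList`/`input` (`role`, `ref`) and `param` (`name`,
#' `value`) elements, followed by `outputList`/`output` (`ref`). Input
#' references must resolve to `"input"` or an earlier activity's name;
#' module references must exist in the registry.
#'
#' @param path An XML file path, literal XML string, or `xml2` document.
#' @return A list of `process_definition` objects.
#' @export
parse_process_definition <- function(path) {
  doc <- if (inherits(path, "xml_document")) path else xml2::read_xml(path)
  procs <- xml2::xml_find_all(doc, ".//process")
  if (!length(procs)) stop("parse_process_definition(): no <process> elements")
  lapply(procs, function(p) {
    pname <- xml2::xml_attr(p, "name")
    acts <- xml2::xml_find_all(p, "./moduleList/activity")
    if (!length(acts)) {
      stop("process '", pname, "': empty moduleList")
    }
    seen <- "input"
    activities <- lapply(acts, function(a) {
      aname <- xml2::xml_attr(a, "activityName")
      mod <- xml2::xml_attr(a, "module")
      path_str <- paste0("process[", pname, "]/activity[", aname, "]")
      if (!exists(mod, envir = .hfo_registry, inherits = FALSE)) {
        stop(path_str, ": unknown activity module '", mod, "'")
      }
      ins <- xml2::xml_find_all(a, "./inputList/input")
      input_list <- lapply(ins, function(inp) {
        ref <- xml2::xml_attr(inp, "ref")
        if (!ref %in% seen) {
          stop(path_str, "/input: reference '", ref,
               "' does not resolve to the primary input or an earlier activity")
        }
        list(role = xml2::xml_attr(inp, "role") %||% "primary", ref = ref)
      })
      pars <- xml2::xml_find_all(a, "./param")
      params <- stats::setNames(
        lapply(pars, function(pp) xml2::xml_attr(pp, "value")),
        vapply(pars, function(pp) xml2::xml_attr(pp, "name"), character(1)))
      seen <<- c(seen, aname)
      list(activity_name = aname, module_ref = mod,
           input_list = input_list, params = params)
    })
    outs <- xml2::xml_find_all(p, "./outputList/output")
    output_list <- vapply(outs, function(o) xml2::xml_attr(o, "ref"), character(1))
    for (ref in output_list) {
      if (!ref %in% seen) {
        stop("process '", pname, "'/outputList: unknown reference '", ref, "'")
      }
    }
    structure(list(name = pname,
                   reference = xml2::xml_attr(p, "reference") %||% "",
                   activities = activities, output_list = output_list),
              class = "process_definition")
  })
}

#' Serialize process definitions to XML
#' @param defs A list of `process_definition` objects (or one).
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_process_definition <- function(defs, path) {
  if (inherits(defs, "process_definition")) defs <- list(defs)
  root <- xml2::xml_new_root("processList")
  for (d in defs) {
    p <- xml2::xml_add_child(root, "process", name = d$name,
                             reference = d$reference)
    ml <- xml2::xml_add_child(p, "moduleList")
    for (a in d$activities) {
      an <- xml2::xml_add_child(ml, "activity", activityName = a$activity_name,
                                module = a$module_ref)
      il <- xml2::xml_add_child(an, "inputList")
      for (inp in a$input_list) {
        xml2::xml_add_child(il, "input", role = inp$role, ref = inp$ref)
      }
      for (nm in names(a$params)) {
        xml2::xml_add_child(an, "param", name = nm,
                            value = as.character(a$params[[nm]]))
      }
    }
    ol <- xml2::xml_add_child(p, "outputList")
    for (ref in d$output_list) xml2::xml_add_child(ol, "output", ref = ref)
  }
  xml2::write_xml(root, path)
  invisible(path)
}

#' Execute a process definition
#'
#' Activities run strictly in definition order; each receives the
#' accumulated data nodes resolved through its input list and appends its
#' output node. On the first failure an `hfo_error_vector` (activity name,
#' stage, message) is returned and no outputs are registered. Activities
#' never mutate their inputs.
#'
#' @param def A `process_definition`.
#' @param input The primary input: an `hfo_recording`, or a list with
#'   `recording` and optionally `events`.
#' @param params Optional parameter set: a named list
#'   `activity_name -> named parameter list`, overriding definition and
#'   schema defaults.
#' @param monitor Optional callback `(activity_name, stage)` with stage
#'   `"start"` or `"done"`.
#' @return On success a list with `outputs` (nodes named in the output
#'   list) and `nodes` (all nodes); on failure an `hfo_error_vector`.
#' @export
run_process <- function(def, input, params = NULL, monitor = NULL) {
  stopifnot(inherits(def, "process_definition"))
  if (inherits(input, "hfo_recording")) input <- list(recording = input)
  nodes <- list(input = node("input", "recording", input$recording))
  if (!is.null(input$events)) {
    nodes$input_events <- node("input_events", "events", input$events)
  }
  for (a in def$activities) {
    if (!is.null(monitor)) monitor(a$activity_name, "start")
    reg <- get(a$module_ref, envir = .hfo_registry)
    p <- schema_defaults(reg$schema)
    for (nm in names(a$params)) p[[nm]] <- a$params[[nm]]
    for (nm in names(params[[a$activity_name]])) {
      p[[nm]] <- params[[a$activity_name]][[nm]]
    }
    inputs <- list()
    for (inp in a$input_list) {
      src <- if (identical(inp$ref, "input")) nodes$input else nodes[[inp$ref]]
      if (is.null(src)) {
        return(error_vector(a$activity_name, "input-resolution",
                            paste0("unresolved input reference '", inp$ref, "'")))
      }
      role <- inp$role
      if (role == "features" && !is.null(inputs$features)) {
        inputs$features <- c(if (inherits(inputs$features, "list"))
          inputs$features else list(inputs$features), list(src))
      } else {
        inputs[[role]] <- src
      }
    }
    # default wiring: events-consuming activities see the latest events node
    if (is.null(inputs$events)) {
      ev_nodes <- Filter(function(n) n$kind == "events", nodes)
      if (length(ev_nodes)) inputs$events <- ev_nodes[[length(ev_nodes)]]
    }
    out <- tryCatch(
      reg$factory(inputs, p),
      error = function(e) structure(conditionMessage(e), class = "activity_failure"))
    if (inherits(out, "activity_failure")) {
      return(error_vector(a$activity_name, "execute", unclass(out)))
    }
    nodes[[a$activity_name]] <- node(a$activity_name, reg$kind, out)
    if (!is.null(monitor)) monitor(a$activity_name, "done")
  }
  outputs <- nodes[def$output_list]
  list(outputs = outputs, nodes = nodes)
}

error_vector <- function(activity, stage, message) {
  structure(list(list(activity = activity, stage = stage, message = message)),
            class = "hfo_error_vector")
}

#' @export
print.hfo_error_vector <- function(x, ...) {
  for (e in x) {
    cat("activity '", e$activity, "' failed at ", e$stage, ": ", e$message,
        "\n", sep = "")
  }
  invisible(x)
}

#' Store / recall parameter sets
#'
#' Parameter sets are kept in a JSON store keyed by (process name, set
#' identifier) so that a tuned configuration can be recalled by name.
#'
#' @param store Path to the JSON store file (created on first save).
#' @param process Process name.
#' @param id Set identifier.
#' @param params Named list `activity -> named parameter list`.
#' @return `load_parameter_set()` returns the parameter list.
#' @export
save_parameter_set <- function(store, process, id, params) {
  all <- if (file.exists(store)) {
    jsonlite::fromJSON(store, simplifyVector = FALSE)
  } else list()
  key <- paste(process, id, sep = "::")
  all[[key]] <- params
  jsonlite::write_json(all, store, auto_unbox = TRUE, digits = NA)
  invisible(store)
}

#' @rdname save_parameter_set
#' @export
load_parameter_set <- function(store, process, id) {
  all <- jsonlite::fromJSON(store, simplifyVector = FALSE)
  key <- paste(process, id, sep = "::")
  if (is.null(all[[key]])) stop("no parameter set '", id, "' for process '",
                                process, "'")
  all[[key]]
}

#' Path to a bundled predefined process definition
#'
#' @param name Definition file name (without extension); `NULL` lists the
#'   available definitions.
#' @return A file path, or a character vector of names.
#' @export
predefined_process <- function(name = NULL) {
  dir <- system.file("processes", package = "hfokit")
  if (is.null(name)) {
    return(sub("\\.xml$", "", list.files(dir, pattern = "\\.xml$")))
  }
  f <- file.path(dir, paste0(name, ".xml"))
  if (!file.exists(f)) stop("no predefined process '", name, "'")
  f
}
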