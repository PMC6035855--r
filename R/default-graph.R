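#' Free parameters of the default discharge graph
#'
#' The workflow's headline durations (38-minute order lag, 88-minute
#' pharmacy preparation, 43/134/195-minute extra-need paths, the 83-minute
#' add-on lag and the medical-records Weibull and accounting Normal /
#' Lognormal models) are fixed study inputs.  The remaining support-task
#' durations — porter trips, the nurse's phone call, the clinical
#' pharmacist's response and counseling times, the family's trip to settle
#' the bill, the equipment lead time — were not tabulated and are free
#' parameters, initialised from the process narrative and fitted by
#' [calibrate()].  `discharge_params()` returns the uncalibrated initial
#' guesses; `calibrated_params()` returns the fitted values shipped with the
#' package.
#'
#' All values are minutes (means unless suffixed `_sd`).
#' @return named list of parameter values.
#' @export
discharge_params <- function() {
  list(
    prep_sd = 45,              # pharmacy preparation sd (mean fixed at 88)
    porter_trip_mean = 8,      # porter carrying medication to the floor
    file_transport_mean = 6,   # porter carrying the file to accounting
    clearance_return_mean = 6, # porter returning the clearance sheet
    phone_call_mean = 3,       # nurse phoning the clinical pharmacist
    pharmacist_delay_mean = 7, # pharmacist arrival delay after the call
    counseling_mean = 6,       # medication counseling at the bedside
    delivery_mean = 4,         # pharmacist-carried delivery (scenario only)
    family_trip_mean = 40,     # family packs up and goes down to pay
    family_trip_sd = 20,
    equipment_lead_mean = 30,  # lag until the equipment need is acted on
    equipment_lead_sd = 35,
    equipment_handover_mean = 12,
    supplies_floor_mean = 45,  # on-floor supplies delivery (scenario only)
    departure_mean = 11        # packing up and escorting the patient out
  )
}

#' @rdname discharge_params
#' @export
calibrated_params <- function() {
  path <- system.file("extdata", "calibrated_params.json",
                      package = "dischargesim")
  if (!nzchar(path)) stop("calibrated parameter file not found", call. = FALSE)
  fitted <- jsonlite::read_json(path, simplifyVector = TRUE)
  p <- discharge_params()
  p[names(fitted)] <- fitted
  p
}

# lognormal with cv 0.35 unless an explicit sd is given
ln <- function(mean, sd = 0.35 * mean) duration_model("lognormal", c(mean, sd))

#' Build the default discharge process graph
#'
#' Constructs the ward's discharge workflow.  Two main branches start at the
#' signed discharge order and run in parallel:
#'
#' * the **medication branch** — the medication order follows the discharge
#'   order after about 38 minutes; the pharmacy prepares it (88 minutes on
#'   average), a porter carries it up, the nurse phones the clinical
#'   pharmacist, who counsels the patient;
#' * the **paperwork branch** — the medical-records officer processes the
#'   file (Weibull(1.7374, 22.091) minutes), a porter takes it to
#'   accounting, where nothing happens until the patient's family arrives to
#'   pay; settlement then takes a Normal(1.1087, 1.43610) delay plus a
#'   Lognormal(2.39750, 2.24560) attention time, and the clearance sheet is
#'   returned to the floor.
#'
#' Conditional paths join before the patient leaves: an outpatient narcotics
#' prescription (40% of patients, 43 minutes), equipment arrangement (16%,
#' 134 minutes plus handover), a supplies trip to the outpatient clinic
#' after the file is closed (5%, 195 minutes), and an add-on medication
#' order 83 minutes after the first prescription (16%) that repeats the
#' pharmacy loop.  The patient leaves when every enabled branch has
#' finished.
#'
#' @param params named parameter list, see [discharge_params()]; defaults to
#'   the shipped calibrated fit.
#' @param needs a [need_probabilities()].
#' @return a validated [process_graph()].
#' @examples
#' g <- build_default_graph()
#' validate_graph(g)   # character(0)
#' @export
build_default_graph <- function(params = calibrated_params(),
                                needs = need_probabilities()) {
  p <- utils::modifyList(discharge_params(), params)
  acts <- list(
    activity("discharge_order", duration_model("fixed", 0),
             performer_note = "specialist signs the discharge order"),
    activity("medication_order", duration_model("fixed", 0),
             predecessors = "discharge_order",
             start_offset = ln(38, 10),
             performer_note = "doctor writes the prescription; nurse faxes it"),
    activity("pharmacy_preparation", ln(88, p$prep_sd),
             resources = c(pharmacy = 1L),
             predecessors = "medication_order",
             performer_note = "pharmacy prepares the medication"),
    activity("porter_transport_medication", ln(p$porter_trip_mean),
             resources = c(porter = 1L),
             predecessors = "pharmacy_preparation",
             performer_note = "porter delivers medication to the nurses' station"),
    activity("nurse_phone_call", ln(p$phone_call_mean, 1),
             predecessors = "porter_transport_medication",
             performer_note = "nurse contacts the clinical pharmacist"),
    activity("pharmacist_counseling", ln(p$counseling_mean),
             resources = c(pharmacist = 1L),
             predecessors = "nurse_phone_call",
             start_offset = ln(p$pharmacist_delay_mean,
                               0.5 * p$pharmacist_delay_mean),
             performer_note = "clinical pharmacist counsels the patient"),
    activity("medical_records_processing",
             duration_model("weibull", c(1.7374, 22.091)),
             resources = c(medical_records = 1L),
             predecessors = "discharge_order",
             performer_note = "medical-records officer closes the file"),
    activity("file_to_accounting", ln(p$file_transport_mean),
             resources = c(porter = 1L),
             predecessors = "medical_records_processing",
             performer_note = "porter takes the file to accounting"),
    activity("family_payment_trip",
             ln(p$family_trip_mean, p$family_trip_sd),
             predecessors = "medical_records_processing",
             performer_note = "family packs, goes down and queues to pay"),
    activity("accounting_settlement",
             duration_model("lognormal", c(2.39750, 2.24560)),
             resources = c(accounting = 1L),
             predecessors = c("file_to_accounting", "family_payment_trip"),
             start_offset = duration_model("normal", c(1.1087, 1.43610)),
             performer_note = "file waits for the family; accountant settles the bill"),
    activity("clearance_return", ln(p$clearance_return_mean),
             resources = c(porter = 1L),
             predecessors = "accounting_settlement",
             performer_note = "clearance sheet returned to the floor"),
    # written by the physician early or late at their discretion; modelled
    # from the discharge order so it overlaps the main medication flow
    activity("narcotics_prescription", ln(43, 14),
             predecessors = "discharge_order",
             condition = "narcotics",
             performer_note = "outpatient controlled-drug prescription handled"),
    activity("equipment_arrangement", ln(134, 40),
             predecessors = "discharge_order",
             start_offset = ln(p$equipment_lead_mean, p$equipment_lead_sd),
             condition = "equipment",
             performer_note = "social worker arranges equipment purchase"),
    activity("equipment_handover", ln(p$equipment_handover_mean, 4),
             predecessors = "equipment_arrangement",
             condition = "equipment",
             performer_note = "equipment delivered and explained"),
    # the trip happens at the end of the stay: the family can only buy
    # supplies once the inpatient file is closed and the patient is ready
    activity("supplies_outpatient_trip", ln(195, 50),
             predecessors = c("pharmacist_counseling",
                              "accounting_settlement"),
             condition = "supplies",
             performer_note = "family opens an outpatient file to buy supplies"),
    activity("addon_medication_order", duration_model("fixed", 0),
             predecessors = "medication_order",
             start_offset = ln(83, 15),
             condition = "addon",
             performer_note = "doctor orders an add-on medication"),
    activity("addon_preparation", ln(88, p$prep_sd),
             resources = c(pharmacy = 1L),
             predecessors = "addon_medication_order",
             condition = "addon",
             performer_note = "pharmacy prepares the add-on order"),
    activity("addon_transport", ln(p$porter_trip_mean),
             resources = c(porter = 1L),
             predecessors = "addon_preparation",
             condition = "addon",
             performer_note = "porter delivers the add-on medication"),
    activity("addon_counseling", ln(p$counseling_mean),
             resources = c(pharmacist = 1L),
             predecessors = "addon_transport",
             start_offset = ln(p$pharmacist_delay_mean,
                               0.5 * p$pharmacist_delay_mean),
             condition = "addon",
             performer_note = "counseling repeated for the add-on order"),
    activity("patient_leaves", ln(p$departure_mean, 4),
             predecessors = c("pharmacist_counseling", "clearance_return",
                              "narcotics_prescription", "equipment_handover",
                              "supplies_outpatient_trip", "addon_counseling"),
             performer_note = "patient leaves the room")
  )
  # capacities sized so that daily load stays below capacity: the 88-minute
  # pharmacy turnaround already includes the central pharmacy's internal
  # queue (8 parallel work streams), and records officers work per floor.
  pools <- list(
    resource_pool("porter", 1L),
    resource_pool("pharmacist", 1L),
    resource_pool("pharmacy", 8L),
    resource_pool("medical_records", 3L),
    resource_pool("accounting", 2L)
  )
  g <- process_graph(acts, pools, needs, arrivals_per_day = 24,
                     arrival_window = 480,
                     end_activity = "patient_leaves", params = p)
  stopifnot(length(validate_graph(g)) == 0L)
  g
}
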