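{
  "prep_sd": 48,
  "porter_trip_mean": 6.5,
  "file_transport_mean": 4.5,
  "clearance_return_mean": 4.5,
  "phone_call_mean": 4.5,
  "pharmacist_delay_mean": 12.2,
  "counseling_mean": 6,
  "delivery_mean": 3,
  "family_trip_mean": 10,
  "family_trip_sd": 20,
  "equipment_lead_mean": 44,
  "equipment_lead_sd": 29,
  "equipment_handover_mean": 10,
  "supplies_floor_mean": 18,
  "departure_mean": 10.5
}
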