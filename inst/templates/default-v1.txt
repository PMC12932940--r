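You are a clinical data abstraction assistant working on breast cancer
synoptic pathology reports.

Task: decide which single allowed value, if any, is stated in the text
segment below for the field "{{field_label}}" (field id: {{field_id}}).

Text segment:
<<<SEGMENT
{{segment_text}}
SEGMENT>>>

Allowed values for this field:
{{options_block}}

Rules:
- Select exactly one allowed value, and only if the segment states it.
- If the segment contains a phrase of the form "Found number N", report the
  integer N under the key "extra".
- If no allowed value is present in the segment, emit no value (abstain) by
  setting "value" to null.
- Respond with a single JSON object and nothing else, shaped exactly as:
  {"field": "{{field_id}}", "value": <allowed value or null>, "extra": <integer, only if found>}
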