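name: multicomponent-27h
total_hours: 27.0
components:
- id: PE
  label: Participatory ergonomics
- id: PT
  label: Physical training
- id: CBT
  label: Cognitive behavioural training
sessions:
- id: PE_KICKOFF
  component: PE
  duration_hours: 1.0
  receipt_mode: individual
  has_intensity: no
  criteria: [PE_KICKOFF_c1, PE_KICKOFF_c2, PE_KICKOFF_c3, PE_KICKOFF_c4, PE_KICKOFF_c5]
- id: PE_WG1
  component: PE
  duration_hours: 2.0
  receipt_mode: team
  has_intensity: no
  criteria: [PE_WG1_c1, PE_WG1_c2, PE_WG1_c3, PE_WG1_c4]
- id: PE_WG2
  component: PE
  duration_hours: 2.0
  receipt_mode: team
  has_intensity: no
  criteria: [PE_WG2_c1, PE_WG2_c2, PE_WG2_c3, PE_WG2_c4]
- id: PE_EVAL1
  component: PE
  duration_hours: 2.0
  receipt_mode: team
  has_intensity: no
  criteria: [PE_EVAL1_c1, PE_EVAL1_c2, PE_EVAL1_c3, PE_EVAL1_c4]
- id: PE_EVAL2
  component: PE
  duration_hours: 2.0
  receipt_mode: team
  has_intensity: no
  criteria: [PE_EVAL2_c1, PE_EVAL2_c2, PE_EVAL2_c3, PE_EVAL2_c4]
- id: PT_W01
  component: PT
  duration_hours: 1.0
  receipt_mode: individual
  has_intensity: yes
  criteria: [PT_W01_c1, PT_W01_c2]
- id: PT_W02
  component: PT
  duration_hours: 1.0
  receipt_mode: individual
  has_intensity: yes
  criteria: [PT_W02_c1, PT_W02_c2]
- id: PT_W03
  component: PT
  duration_hours: 1.0
  receipt_mode: individual
  has_intensity: yes
  criteria: [PT_W03_c1, PT_W03_c2]
- id: PT_W04
  component: PT
  duration_hours: 1.0
  receipt_mode: individual
  has_intensity: yes
  criteria: [PT_W04_c1, PT_W04_c2]
- id: PT_W05
  component: PT
  duration_hours: 1.0
  receipt_mode: individual
  has_intensity: yes
  criteria: [PT_W05_c1, PT_W05_c2]
- id: PT_W06
  component: PT
  duration_hours: 1.0
  receipt_mode: individual
  has_intensity: yes
  criteria: [PT_W06_c1, PT_W06_c2]
- id: PT_W07
  component: PT
  duration_hours: 1.0
  receipt_mode: individual
  has_intensity: yes
  criteria: [PT_W07_c1, PT_W07_c2]
- id: PT_W08
  component: PT
  duration_hours: 1.0
  receipt_mode: individual
  has_intensity: yes
  criteria: [PT_W08_c1, PT_W08_c2]
- id: PT_W09
  component: PT
  duration_hours: 1.0
  receipt_mode: individual
  has_intensity: yes
  criteria: [PT_W09_c1, PT_W09_c2]
- id: PT_W10
  component: PT
  duration_hours: 1.0
  receipt_mode: individual
  has_intensity: yes
  criteria: [PT_W10_c1, PT_W10_c2]
- id: PT_W11
  component: PT
  duration_hours: 1.0
  receipt_mode: individual
  has_intensity: yes
  criteria: [PT_W11_c1, PT_W11_c2]
- id: PT_W12
  component: PT
  duration_hours: 1.0
  receipt_mode: individual
  has_intensity: yes
  criteria: [PT_W12_c1, PT_W12_c2]
- id: CBT_WS1
  component: CBT
  duration_hours: 3.0
  receipt_mode: individual
  has_intensity: no
  criteria: [CBT_WS1_c1, CBT_WS1_c2, CBT_WS1_c3, CBT_WS1_c4, CBT_WS1_c5]
- id: CBT_WS2
  component: CBT
  duration_hours: 3.0
  receipt_mode: individual
  has_intensity: no
  criteria: [CBT_WS2_c1, CBT_WS2_c2, CBT_WS2_c3, CBT_WS2_c4, CBT_WS2_c5]
representation_schedule:
- min_size: 1.0
  max_size: 4.0
  required: 2
- min_size: 5.0
  max_size: 9.0
  required: 3
- min_size: 10.0
  max_size: 14.0
  required: 4
- min_size: 15.0
  max_size: 19.0
  required: 5
- min_size: 20.0
  max_size: .inf
  required: 6
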