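<?xml version="1.0" encoding="UTF-8"?>
<trial_set>
  <trial id="T0001" sponsor_type="Industry" intervention="Drug A">
    <arm id="A1" title="Active" enrolled="120" mean_age="45.5" overall_affected="37">
      <event term="Nausea" soc="Gastrointestinal disorders" serious="false" subjects_affected="12" subjects_at_risk="120"/>
      <event term="Headache" serious="false" subjects_affected="20" subjects_at_risk="120"/>
      <event term="Myocardial infarction" soc="Cardiac disorders" serious="true" subjects_affected="1" subjects_at_risk="120"/>
    </arm>
    <arm id="A2" title="Placebo" enrolled="118" mean_age="46.1" overall_affected="21">
      <event term="Headache" serious="false" subjects_affected="15" subjects_at_risk="118"/>
      <event term="Fatigue" serious="false" subjects_affected="9" subjects_at_risk="118"/>
    </arm>
  </trial>
  <trial id="T0002" sponsor_type="NIH" intervention="Drug B">
    <arm id="A1" title="Single arm" enrolled="64" mean_age="8.2">
      <event term="Pharyngitis" soc="Infections and infestations" serious="false" subjects_affected="7" subjects_at_risk="64"/>
      <event term="Otitis media" serious="false" subjects_affected="4" subjects_at_risk="64"/>
    </arm>
  </trial>
</trial_set>
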