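<processList>
  <process name="FIR, Hilbert envelope, power spectral density analysis"
           reference="Burnos Hilbert-envelope detector; S-transform rule">
    <moduleList>
      <activity activityName="FIR band-pass" module="fir_filter">
        <inputList><input role="primary" ref="input"/></inputList>
        <param name="low_hz" value="80"/>
        <param name="high_hz" value="250"/>
      </activity>
      <activity activityName="Hilbert detection" module="hilbert_detector">
        <inputList><input role="primary" ref="FIR band-pass"/></inputList>
      </activity>
      <activity activityName="Stockwell classification" module="stockwell_classifier">
        <inputList>
          <input role="primary" ref="input"/>
          <input role="events" ref="Hilbert detection"/>
        </inputList>
      </activity>
    </moduleList>
    <outputList><output ref="Stockwell classification"/></outputList>
  </process>
</processList>
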