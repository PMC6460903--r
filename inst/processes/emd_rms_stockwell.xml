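<processList>
  <process name="EMD, RMS, power spectral density analysis"
           reference="EMD high-pass; Staba RMS detector; S-transform rule">
    <moduleList>
      <activity activityName="EMD high-pass" module="emd_filter">
        <inputList><input role="primary" ref="input"/></inputList>
        <param name="first_imf" value="1"/>
        <param name="n_imfs" value="2"/>
      </activity>
      <activity activityName="RMS detection" module="rms_detector">
        <inputList><input role="primary" ref="EMD high-pass"/></inputList>
      </activity>
      <activity activityName="Stockwell classification" module="stockwell_classifier">
        <inputList>
          <input role="primary" ref="input"/>
          <input role="events" ref="RMS detection"/>
        </inputList>
      </activity>
    </moduleList>
    <outputList><output ref="Stockwell classification"/></outputList>
  </process>
</processList>
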