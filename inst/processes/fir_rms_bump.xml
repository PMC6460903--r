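<processList>
  <process name="FIR, RMS, bump modeling"
           reference="Staba RMS detector; bump-modeling classifier (reserved)">
    <moduleList>
      <activity activityName="FIR band-pass" module="fir_filter">
        <inputList><input role="primary" ref="input"/></inputList>
        <param name="low_hz" value="80"/>
        <param name="high_hz" value="250"/>
      </activity>
      <activity activityName="RMS detection" module="rms_detector">
        <inputList><input role="primary" ref="FIR band-pass"/></inputList>
      </activity>
      <activity activityName="Bump classification" module="bump_modeling">
        <inputList>
          <input role="primary" ref="input"/>
          <input role="events" ref="RMS detection"/>
        </inputList>
      </activity>
    </moduleList>
    <outputList><output ref="Bump classification"/></outputList>
  </process>
</processList>
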