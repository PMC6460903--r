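<processList>
  <process name="FIR, Hilbert envelope, SVM"
           reference="Burnos Hilbert-envelope detector; RBF-SVM classifier">
    <moduleList>
      <activity activityName="FIR band-pass" module="fir_filter">
        <inputList><input role="primary" ref="input"/></inputList>
        <param name="low_hz" value="80"/>
        <param name="high_hz" value="250"/>
      </activity>
      <activity activityName="Hilbert detection" module="hilbert_detector">
        <inputList><input role="primary" ref="FIR band-pass"/></inputList>
      </activity>
      <activity activityName="Time features" module="time_features">
        <inputList>
          <input role="primary" ref="FIR band-pass"/>
          <input role="events" ref="Hilbert detection"/>
        </inputList>
      </activity>
      <activity activityName="Spectral features" module="spectral_features">
        <inputList>
          <input role="primary" ref="FIR band-pass"/>
          <input role="events" ref="Hilbert detection"/>
        </inputList>
      </activity>
      <activity activityName="SVM classification" module="svm_classifier">
        <inputList>
          <input role="features" ref="Time features"/>
          <input role="features" ref="Spectral features"/>
        </inputList>
      </activity>
    </moduleList>
    <outputList><output ref="SVM classification"/></outputList>
  </process>
</processList>
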