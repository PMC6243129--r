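<?xml version="1.0" encoding="UTF-8"?>
<Lems>
  <Dimension name="dimensionless"/>
  <Dimension name="time" t="1"/>
  <Dimension name="current" i="1"/>
  <Unit symbol="ms" dimension="time" power="-3"/>
  <Unit symbol="nA" dimension="current" power="-9"/>
  <ComponentType name="izhikevichCell">
    <Parameter name="a" dimension="dimensionless"/>
    <Parameter name="b" dimension="dimensionless"/>
    <Parameter name="c" dimension="dimensionless"/>
    <Parameter name="d" dimension="dimensionless"/>
    <Parameter name="vpeak" dimension="dimensionless"/>
    <Parameter name="tscale" dimension="time"/>
    <Parameter name="iscale" dimension="current"/>
    <Requirement name="iSyn" dimension="current"/>
    <Exposure name="v"/>
    <Exposure name="u"/>
    <EventPort name="spike" direction="out"/>
    <Dynamics>
      <StateVariable name="v" dimension="dimensionless"/>
      <StateVariable name="u" dimension="dimensionless"/>
      <DerivedVariable name="inorm" value="iSyn / iscale"/>
      <TimeDerivative variable="v"
        value="(0.04 * v^2 + 5 * v + 140 - u + inorm) / tscale"/>
      <TimeDerivative variable="u" value="a * (b * v - u) / tscale"/>
      <OnStart>
        <StateAssignment variable="v" value="c"/>
        <StateAssignment variable="u" value="b * c"/>
      </OnStart>
      <OnCondition test="v .geq. vpeak">
        <StateAssignment variable="v" value="c"/>
        <StateAssignment variable="u" value="u + d"/>
        <EventOut port="spike"/>
      </OnCondition>
    </Dynamics>
  </ComponentType>
  <Component id="cell" type="izhikevichCell"
    a="0.02" b="0.2" c="-65" d="8" vpeak="30"
    tscale="1 ms" iscale="1 nA"/>
  <Component id="stim" type="pulseGenerator"
    delay="20 ms" duration="150 ms" amplitude="8 nA"/>
  <ModelAssembly root="cell">
    <VariableLink from="stim/i" to="cell/iSyn"/>
  </ModelAssembly>
</Lems>
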