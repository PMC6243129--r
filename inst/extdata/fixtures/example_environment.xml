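<?xml version="1.0" encoding="UTF-8"?>
<behavioralExperiment>
  <experimentDuration>1000</experimentDuration>
  <experimentDefinition/>
  <environmentDefinition>
    <wormStatus>
      <wormData>
        <mutationId>N2</mutationId>
        <age>1</age>
        <sex>hermaphrodite</sex>
        <stage>L1</stage>
        <hoursWithoutFood>1</hoursWithoutFood>
        <bodyLength>1</bodyLength>
        <bodyDiameter>80</bodyDiameter>
      </wormData>
      <wormLocation>
        <x>10</x>
        <y>5</y>
        <orientation>45</orientation>
      </wormLocation>
    </wormStatus>
    <plateConf>
      <shape>cylindrical</shape>
      <borderHeight>15</borderHeight>
      <radius>50</radius>
      <substrate>A</substrate>
      <dryness>1</dryness>
      <lid>false</lid>
    </plateConf>
    <obstaclesConf>
      <obstacle>
        <shape>cylinder</shape>
        <height>5</height>
        <radius>5</radius>
        <stiffness>43.2</stiffness>
        <distanceX>10</distanceX>
        <distanceY>-15</distanceY>
        <angle>30</angle>
      </obstacle>
    </obstaclesConf>
    <crowdingConf>
      <wormCount>1</wormCount>
      <distributionIndex>0</distributionIndex>
    </crowdingConf>
  </environmentDefinition>
</behavioralExperiment>
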